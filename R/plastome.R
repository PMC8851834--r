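#' Detect the plastome quadripartite architecture
#'
#' Finds the maximal pair of large inverted repeats (>= `min_ir_len`, near
#' identity) via self homology on the doubled circle, then derives the two
#' single-copy regions between them. Coordinates are rotated so the large
#' single-copy region (LSC, the longer of the two by naming convention)
#' starts at 0, giving the canonical LSC-IRb-SSC-IRa order. Returns `NULL`
#' when no qualifying inverted pair exists (the IR-loss situation of dodder
#' plastomes).
#'
#' @param plastome one-row circular `genome_set`.
#' @param min_ir_len minimum IR length in bp.
#' @param min_identity minimum IR pair identity (plastome IRs are rarely
#'   perfectly identical; default 99.9).
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @return A `quadripartite_map` (list with `lsc`, `irb`, `ssc`, `ira` as
#'   `c(start, end)` in the rotated frame, `ir_len`, `ir_identity`,
#'   `rotation` = offset of the rotated origin on the input sequence,
#'   `genome_id`, `length`), or `NULL`.
#' @export
detect_ir <- function(plastome, min_ir_len = 1000L, min_identity = 99.9,
                      th = thresholds(), params = alignment_params()) {
  g <- as_genome(plastome)
  if (!identical(g$topology[1], "circular")) {
    stop("IR detection expects a circular plastome", call. = FALSE)
  }
  L <- g$length[1]
  ir_core <- function(seqstr) {
    gg <- genome_set(g$id[1], seqstr, topology = "circular")
    h <- self_hits(gg, th = th, params = params)
    h <- h[h$strand == "-" & h$aln_len >= min_ir_len &
             h$identity >= min_identity, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h[order(-h$aln_len, -h$bitscore), , drop = FALSE][1, ]
  }
  # the query side of a self-search is linear, so an IR crossing the origin
  # would be found fragmented; scanning a half-rotated copy as well
  # guarantees one frame sees each IR copy contiguously
  shift <- L %/% 2L
  rotated <- paste0(substring(g$seq[1], shift + 1L, L),
                    substring(g$seq[1], 1L, shift))
  h1 <- ir_core(g$seq[1])
  h2 <- ir_core(rotated)
  if (is.null(h1) && is.null(h2)) return(NULL)
  use2 <- is.null(h1) || (!is.null(h2) && h2$aln_len > h1$aln_len)
  hit <- if (use2) h2 else h1
  # two repeat copies on the circle (forward coordinates, may wrap)
  span1 <- c(hit$q_start, hit$q_end)
  span2 <- c(hit$s_start, hit$s_end)
  if (use2) {
    span1 <- (span1 + shift) %% L
    span2 <- (span2 + shift) %% L
  }
  gap_len <- function(from, to) (to - from) %% L
  # single-copy regions between the repeat copies
  sc1 <- c(span1[2] %% L, span2[1])          # after copy1, before copy2
  sc2 <- c(span2[2] %% L, span1[1])          # after copy2, before copy1
  len1 <- gap_len(sc1[1], sc1[2])
  len2 <- gap_len(sc2[1], sc2[2])
  if (len1 == 0 || len2 == 0) return(NULL)   # tandem, not quadripartite
  if (len1 >= len2) {
    lsc_start <- sc1[1]; lsc_len <- len1
    irb <- span2; ssc_len <- len2; ira <- span1
  } else {
    lsc_start <- sc2[1]; lsc_len <- len2
    irb <- span1; ssc_len <- len1; ira <- span2
  }
  ir_len <- gap_len(irb[1], irb[2])
  structure(list(
    genome_id = g$id[1], length = L,
    lsc = c(0L, lsc_len),
    irb = c(lsc_len, lsc_len + ir_len),
    ssc = c(lsc_len + ir_len, lsc_len + ir_len + ssc_len),
    ira = c(lsc_len + ir_len + ssc_len, lsc_len + 2L * ir_len + ssc_len),
    ir_len = ir_len, ir_identity = hit$identity,
    rotation = lsc_start %% L
  ), class = "quadripartite_map")
}

#' @export
print.quadripartite_map <- function(x, ...) {
  cat("Quadripartite plastome map of", x$genome_id,
      sprintf("(%d bp; IR %d bp at %.3f%% identity)\n",
              x$length, x$ir_len, x$ir_identity))
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("  %-4s %7d..%-7d (%d bp)\n", toupper(r), x[[r]][1], x[[r]][2],
                x[[r]][2] - x[[r]][1]))
  }
  cat("  rotation offset on input sequence:", x$rotation, "\n")
  invisible(x)
}

#' @describeIn detect_ir region table of a quadripartite map.
#' @param x a `quadripartite_map`.
#' @param ... unused.
#' @export
tidy.quadripartite_map <- function(x, ...) {
  tibble::tibble(
    genome_id = x$genome_id,
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(x$lsc[1], x$irb[1], x$ssc[1], x$ira[1]),
    end = c(x$lsc[2], x$irb[2], x$ssc[2], x$ira[2])
  ) |> dplyr::mutate(length = .data$end - .data$start)
}

#' Genes at the IR junctions
#'
#' For each of the four junctions (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC),
#' reports the gene overlapping the junction (with the offset by which it
#' extends into the IR side, where applicable) or the nearest gene with its
#' signed distance (negative = gene ends before the junction). Genes lying
#' fully inside IRb are additionally reported as their mirrored IRa
#' duplicates.
#'
#' @param qmap a `quadripartite_map` from [detect_ir()].
#' @param genes a `gene_models` tibble with coordinates on the *input*
#'   plastome frame (they are rotated internally using `qmap$rotation`).
#' @return A tibble with `junction`, `gene_id`, `gene_start`, `gene_end`
#'   (rotated frame), `overlaps`, `distance` (0 when overlapping),
#'   `offset_into_ir`, `ir_duplicate`.
#' @export
junction_report <- function(qmap, genes) {
  L <- qmap$length
  rot <- function(p) (p - qmap$rotation) %% L
  g <- tibble::tibble(gene_id = genes$gene_id,
                      start = rot(genes$start), end = rot(genes$end))
  # a rotated gene may wrap; normalise end
  g$end[g$end < g$start] <- g$end[g$end < g$start] + L
  junctions <- tibble::tibble(
    junction = c("LSC/IRb", "IRb/SSC", "SSC/IRa", "IRa/LSC"),
    pos = c(qmap$irb[1], qmap$ssc[1], qmap$ira[1], qmap$ira[2] %% L),
    ir_side = c("right", "left", "right", "left")  # which side is the IR
  )
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    jpos <- junctions$pos[i]
    ov <- g$start < jpos & g$end > jpos
    if (any(ov)) {
      gg <- g[ov, ][1, ]
      off <- if (junctions$ir_side[i] == "right") gg$end - jpos else jpos - gg$start
      tibble::tibble(junction = junctions$junction[i], gene_id = gg$gene_id,
                     gene_start = gg$start, gene_end = gg$end,
                     overlaps = TRUE, distance = 0L,
                     offset_into_ir = as.integer(off))
    } else {
      d <- ifelse(g$end <= jpos, g$end - jpos, g$start - jpos)
      k <- which.min(abs(d))
      tibble::tibble(junction = junctions$junction[i], gene_id = g$gene_id[k],
                     gene_start = g$start[k], gene_end = g$end[k],
                     overlaps = FALSE, distance = as.integer(d[k]),
                     offset_into_ir = NA_integer_)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$ir_duplicate <- FALSE
  # genes fully inside IRb: report the mirrored IRa copy
  inside <- g$start >= qmap$irb[1] & g$end <= qmap$irb[2]
  if (any(inside)) {
    gg <- g[inside, , drop = FALSE]
    mirror_start <- qmap$ira[1] + (qmap$irb[2] - gg$end)
    mirror_end <- qmap$ira[1] + (qmap$irb[2] - gg$start)
    dup <- tibble::tibble(junction = "IR-internal", gene_id = gg$gene_id,
                          gene_start = as.integer(mirror_start),
                          gene_end = as.integer(mirror_end),
                          overlaps = FALSE, distance = NA_integer_,
                          offset_into_ir = NA_integer_, ir_duplicate = TRUE)
    out <- dplyr::bind_rows(out, dup)
  }
  out
}
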