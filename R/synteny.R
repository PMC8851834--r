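#' Fragment a genome into fixed-length windows
#'
#' Non-overlapping consecutive windows of `synteny_fragment_len` bp (default
#' 50), the "pseudo-gene" device for whole-mitogenome synteny; a trailing
#' remainder shorter than the full length is discarded.
#'
#' @param genome one-row `genome_set` or DNA string.
#' @param th [thresholds()].
#' @return A tibble with `frag_idx` (0-based), `start`, `end`, `seq`.
#' @export
fragment_genome <- function(genome, th = thresholds()) {
  g <- as_genome(genome)
  L <- th$synteny_fragment_len
  n <- g$length[1] %/% L
  if (n == 0) {
    return(tibble::tibble(frag_idx = integer(), start = integer(),
                          end = integer(), seq = character()))
  }
  start <- (seq_len(n) - 1L) * L
  tibble::tibble(frag_idx = seq_len(n) - 1L, start = start, end = start + L,
                 seq = substring(g$seq[1], start + 1L, start + L))
}

#' Map fragment anchors between two genomes
#'
#' Each fragment of genome A is searched against genome B with the full
#' homology engine; the best qualifying hit (identity >= `min_identity` over
#' at least `min_cov` of the fragment) yields one anchor, assigned to the B
#' fragment containing the hit midpoint. With `reciprocal = TRUE` only
#' reciprocal-best pairs are kept.
#'
#' @param a,b one-row `genome_set`s or DNA strings.
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @param word_size seed length for the fragment searches; default 12 keeps
#'   50-mers seedable at a few percent divergence.
#' @param min_identity,min_cov anchor qualification thresholds.
#' @param reciprocal keep only reciprocal-best anchors.
#' @return A tibble of anchors: `a_idx`, `a_start`, `a_end`, `b_idx`,
#'   `b_start`, `b_end`, `strand`, `identity`.
#' @export
anchor_map <- function(a, b, th = thresholds(), params = alignment_params(),
                       word_size = 12L, min_identity = 90, min_cov = 0.8,
                       reciprocal = FALSE) {
  a <- as_genome(a, "A"); b <- as_genome(b, "B")
  L <- th$synteny_fragment_len
  best_of <- function(qa, sb) {
    fr <- fragment_genome(qa, th)
    if (nrow(fr) == 0) return(NULL)
    qset <- genome_set(id = as.character(fr$frag_idx), seq = fr$seq,
                       topology = "linear")
    h <- find_hits(qset, sb, th = th, params = params, word_size = word_size)
    h <- h[h$identity >= min_identity &
             (h$q_end - h$q_start) >= min_cov * L &
             h$s_end > h$s_start, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h <- h[!duplicated(h$query_id), , drop = FALSE]  # sorted best-first
    h$frag_idx <- as.integer(h$query_id)
    h
  }
  ha <- best_of(a, b)
  if (is.null(ha)) {
    return(tibble::tibble(a_idx = integer(), a_start = integer(),
                          a_end = integer(), b_idx = integer(),
                          b_start = integer(), b_end = integer(),
                          strand = character(), identity = numeric()))
  }
  b_idx <- pmin((ha$s_start + ha$s_end) %/% 2L %/% L,
                b$length[1] %/% L - 1L)
  anchors <- tibble::tibble(
    a_idx = ha$frag_idx, a_start = ha$frag_idx * L, a_end = (ha$frag_idx + 1L) * L,
    b_idx = b_idx, b_start = b_idx * L, b_end = (b_idx + 1L) * L,
    strand = ha$strand, identity = ha$identity
  )
  if (reciprocal) {
    hb <- best_of(b, a)
    if (is.null(hb)) return(anchors[0, ])
    a_of_b <- pmin((hb$s_start + hb$s_end) %/% 2L %/% L,
                   a$length[1] %/% L - 1L)
    rec <- stats::setNames(a_of_b, hb$frag_idx)
    keep <- !is.na(rec[as.character(anchors$b_idx)]) &
      rec[as.character(anchors$b_idx)] == anchors$a_idx
    anchors <- anchors[keep, , drop = FALSE]
  }
  dplyr::arrange(anchors, .data$a_idx)
}

#' Chain anchors into collinear synteny blocks
#'
#' Repeated weighted longest-increasing (same orientation) or decreasing
#' (inverted) subsequence chaining with a fragment-gap cap; every anchor
#' joins at most one block, and blocks need at least `min_block_anchors`
#' anchors.
#'
#' @param anchors tibble from [anchor_map()].
#' @param max_gap_frags maximum fragment-index gap bridged within a block.
#' @param min_block_anchors minimum anchors per reported block.
#' @return A tibble of blocks sorted by A span: `block_id`, `orientation`
#'   ("same"/"inverted"), `n_anchors`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, plus an `anchor_idx` list-column of row indices into `anchors`.
#' @export
chain_blocks <- function(anchors, max_gap_frags = 10L, min_block_anchors = 5L) {
  empty <- tibble::tibble(block_id = integer(), orientation = character(),
                          n_anchors = integer(), a_start = integer(),
                          a_end = integer(), b_start = integer(),
                          b_end = integer(), anchor_idx = list())
  if (nrow(anchors) == 0) return(empty)
  anchors <- anchors[order(anchors$a_idx), , drop = FALSE]
  avail <- rep(TRUE, nrow(anchors))
  blocks <- list()
  # best chain among available anchors, one orientation at a time
  best_chain <- function(idx, inverted) {
    sub <- anchors[idx, ]
    n <- length(idx)
    score <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        da <- sub$a_idx[i] - sub$a_idx[j]
        db <- if (inverted) sub$b_idx[j] - sub$b_idx[i] else sub$b_idx[i] - sub$b_idx[j]
        ok_strand <- if (inverted) {
          sub$strand[i] == "-" && sub$strand[j] == "-"
        } else {
          sub$strand[i] == "+" && sub$strand[j] == "+"
        }
        if (ok_strand && da > 0 && db > 0 && da <= max_gap_frags &&
            db <= max_gap_frags && score[j] + 1L > score[i]) {
          score[i] <- score[j] + 1L
          prev[i] <- j
        }
      }
    }
    ok <- if (inverted) sub$strand == "-" else sub$strand == "+"
    if (!any(ok)) return(integer())
    i <- which(ok)[which.max(score[ok])]
    chain <- integer()
    while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
    idx[chain]
  }
  repeat {
    idx <- which(avail)
    if (length(idx) < min_block_anchors) break
    ch_same <- best_chain(idx, inverted = FALSE)
    ch_inv <- best_chain(idx, inverted = TRUE)
    ch <- if (length(ch_same) >= length(ch_inv)) ch_same else ch_inv
    inverted <- length(ch_same) < length(ch_inv)
    if (length(ch) < min_block_anchors) break
    avail[ch] <- FALSE
    sub <- anchors[ch, ]
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      orientation = if (inverted) "inverted" else "same",
      n_anchors = length(ch),
      a_start = min(sub$a_start), a_end = max(sub$a_end),
      b_start = min(sub$b_start), b_end = max(sub$b_end),
      anchor_idx = list(ch)
    )
  }
  if (length(blocks) == 0) return(empty)
  out <- dplyr::arrange(dplyr::bind_rows(blocks), .data$a_start)
  tibble::tibble(block_id = seq_len(nrow(out)), out)
}

#' Write anchors in MCscan-compatible format
#'
#' Three tab-separated columns (A fragment, B fragment, score), so results
#' can be cross-checked against external collinearity tools.
#'
#' @param anchors tibble from [anchor_map()].
#' @param path output file.
#' @param prefix_a,prefix_b fragment-name prefixes.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path, prefix_a = "A", prefix_b = "B") {
  writeLines(paste(paste0(prefix_a, "_", anchors$a_idx),
                   paste0(prefix_b, "_", anchors$b_idx),
                   round(anchors$identity), sep = "\t"), path)
  invisible(path)
}
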