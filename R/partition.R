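#' Plastid-like intervals of a mitogenome
#'
#' Bases of the focal mitogenome covered by a hit against any supplied
#' plastome with identity above `plastid_identity_min` (default >90%) and
#' e-value within the ceiling — the mitochondrial plastid DNA (MTPT) rule.
#'
#' @param focal one-row `genome_set` (the focal mitogenome).
#' @param plastomes `genome_set` of one or more plastomes.
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @return A tibble of disjoint intervals (`seq_id`, `start`, `end`).
#' @export
plastid_like_intervals <- function(focal, plastomes, th = thresholds(),
                                   params = alignment_params()) {
  focal <- as_genome(focal)
  if (is.null(plastomes) || nrow(plastomes) == 0) {
    stop("at least one plastome is required", call. = FALSE)
  }
  starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(plastomes))) {
    h <- find_hits(focal, plastomes[i, ], th = th, params = params)
    h <- h[h$identity > th$plastid_identity_min, , drop = FALSE]
    starts <- c(starts, h$q_start); ends <- c(ends, h$q_end)
  }
  r <- reduce_intervals(starts, ends)
  tibble::tibble(seq_id = focal$id[1], start = r$start, end = r$end)
}

#' Repetitive intervals of a genome
#'
#' Union of both sides of self-hits with identity above `repeat_identity_min`
#' (default >95%), the dispersed/inverted repeat rule.
#'
#' @inheritParams plastid_like_intervals
#' @return A tibble of disjoint intervals.
#' @export
repetitive_intervals <- function(focal, th = thresholds(),
                                 params = alignment_params()) {
  focal <- as_genome(focal)
  h <- self_hits(focal, th = th, params = params)
  h <- h[h$identity > th$repeat_identity_min, , drop = FALSE]
  L <- focal$length[1]
  starts <- c(h$q_start, h$s_start)
  ends <- c(h$q_end, h$s_end)
  wrap <- ends < starts
  if (any(wrap)) {
    starts <- c(starts[!wrap], starts[wrap], rep(0L, sum(wrap)))
    ends <- c(ends[!wrap], rep(L, sum(wrap)), ends[wrap])
  }
  ends <- pmin(ends, L)
  r <- reduce_intervals(starts, ends)
  tibble::tibble(seq_id = focal$id[1], start = r$start, end = r$end)
}

#' Conserved intervals of a mitogenome
#'
#' Bases with a qualifying homolog in every other mitogenome of the family
#' set (`scope = "species"`), or in at least one member of every other genus
#' (`scope = "genus"`).
#'
#' @inheritParams plastid_like_intervals
#' @param others `genome_set` of the other family mitogenomes (the focal
#'   genome itself must not be among them).
#' @param scope conservation scope, "species" (default) or "genus".
#' @param max_gap gap-bridging width (bp) when merging hit intervals per
#'   genome.
#' @return A tibble of disjoint intervals.
#' @export
conserved_intervals <- function(focal, others, th = thresholds(),
                                params = alignment_params(),
                                scope = c("species", "genus"), max_gap = 0L) {
  scope <- match.arg(scope)
  focal <- as_genome(focal)
  if (focal$id[1] %in% others$id) {
    stop("family set must not contain the focal genome", call. = FALSE)
  }
  if (nrow(others) < 2) {
    stop("conservation requires at least two other mitogenomes", call. = FALSE)
  }
  cover_one <- function(g) {
    h <- find_hits(focal, g, th = th, params = params)
    reduce_intervals(h$q_start, h$q_end, max_gap)
  }
  to_ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)
  if (scope == "species") {
    covers <- lapply(seq_len(nrow(others)), function(i) to_ir(cover_one(others[i, ])))
  } else {
    covers <- lapply(unique(others$genus), function(gn) {
      members <- others[others$genus == gn, , drop = FALSE]
      ir <- IRanges::IRanges()
      for (i in seq_len(nrow(members))) {
        ir <- IRanges::union(ir, to_ir(cover_one(members[i, ])))
      }
      ir
    })
  }
  acc <- IRanges::IRanges(start = 1L, end = focal$length[1])
  for (ir in covers) acc <- IRanges::intersect(acc, ir)
  tibble::tibble(seq_id = focal$id[1],
                 start = IRanges::start(acc) - 1L, end = IRanges::end(acc))
}

#' Genus- and species-specific intervals
#'
#' Genus/species-specific sequences (GSS): the complement of all qualifying
#' hits of the focal genome against mitogenomes of other genera. When
#' congeners (same-genus members) are present in the family set, the subset
#' with no congener homology either is labelled species-specific.
#'
#' @inheritParams conserved_intervals
#' @param family `genome_set` of the other family mitogenomes, with genus
#'   labels.
#' @return A tibble of disjoint intervals with a `scope` column ("genus" or
#'   "species"); species-specific intervals are a subset of the genus-specific
#'   complement.
#' @export
specific_intervals <- function(focal, family, th = thresholds(),
                               params = alignment_params()) {
  focal <- as_genome(focal)
  if (focal$id[1] %in% family$id) {
    stop("family set must not contain the focal genome", call. = FALSE)
  }
  if (any(is.na(family$genus)) || is.na(focal$genus[1])) {
    stop("genus labels are required for specific-sequence calls", call. = FALSE)
  }
  cover_union <- function(members) {
    starts <- integer(); ends <- integer()
    for (i in seq_len(nrow(members))) {
      h <- find_hits(focal, members[i, ], th = th, params = params)
      starts <- c(starts, h$q_start); ends <- c(ends, h$q_end)
    }
    reduce_intervals(starts, ends)
  }
  L <- focal$length[1]
  full <- IRanges::IRanges(start = 1L, end = L)
  other_genera <- family[family$genus != focal$genus[1], , drop = FALSE]
  congeners <- family[family$genus == focal$genus[1], , drop = FALSE]
  og <- cover_union(other_genera)
  genus_sp <- IRanges::setdiff(full, IRanges::IRanges(og$start + 1L, og$end))
  if (nrow(congeners) > 0) {
    cg <- cover_union(congeners)
    species_sp <- IRanges::setdiff(genus_sp,
                                   IRanges::IRanges(cg$start + 1L, cg$end))
    genus_only <- IRanges::setdiff(genus_sp, species_sp)
    out <- dplyr::bind_rows(
      tibble::tibble(start = IRanges::start(genus_only) - 1L,
                     end = IRanges::end(genus_only), scope = "genus"),
      tibble::tibble(start = IRanges::start(species_sp) - 1L,
                     end = IRanges::end(species_sp), scope = "species")
    )
  } else {
    out <- tibble::tibble(start = IRanges::start(genus_sp) - 1L,
                          end = IRanges::end(genus_sp), scope = "genus")
  }
  out <- out[order(out$start), , drop = FALSE]
  tibble::tibble(seq_id = focal$id[1], out)
}

#' Dissect a mitogenome into five sequence classes
#'
#' Assigns every base of the focal mitogenome to one of CONSERVED (homologs
#' in all other family mitogenomes), PLASTID_LIKE (plastid insertions above
#' 90% identity), REPETITIVE (self-hits above 95% identity), SPECIFIC (no
#' homology to other genera; genus- or/and species-specific) or OTHER (the
#' rest), using the fixed precedence PLASTID_LIKE, then REPETITIVE, then
#' CONSERVED, then SPECIFIC, then OTHER. Contiguous equal-label runs are
#' emitted as segments that tile the genome exactly.
#'
#' @inheritParams plastid_like_intervals
#' @param family `genome_set` of the other family mitogenomes (excluding the
#'   focal genome), with genus labels.
#' @param conserved_scope passed to [conserved_intervals()].
#' @param min_segment optional merge width: segments shorter than this are
#'   absorbed into their longer neighbour (default 1 = no smoothing).
#' @return A `partition_result` object: list with `genome_id`, `length`,
#'   `segments` (tibble `seq_id`, `start`, `end`, `class`), `totals` and
#'   `proportions` (named by class), and the underlying hit-derived interval
#'   sets. Supports [tidy()], [glance()] and [autoplot()].
#' @export
classify_genome <- function(focal, family, plastomes, th = thresholds(),
                            params = alignment_params(),
                            conserved_scope = "species", min_segment = 1L) {
  focal <- as_genome(focal)
  L <- focal$length[1]
  pl <- plastid_like_intervals(focal, plastomes, th, params)
  rp <- repetitive_intervals(focal, th, params)
  cv <- conserved_intervals(focal, family, th, params, scope = conserved_scope)
  sp <- specific_intervals(focal, family, th, params)
  to_ir <- function(df) IRanges::IRanges(df$start + 1L, df$end)
  full <- IRanges::IRanges(1L, L)
  classes <- list(PLASTID_LIKE = to_ir(pl), REPETITIVE = to_ir(rp),
                  CONSERVED = to_ir(cv), SPECIFIC = to_ir(sp))
  segments <- list()
  claimed <- IRanges::IRanges()
  for (cl in names(classes)) {
    own <- IRanges::setdiff(classes[[cl]], claimed)
    claimed <- IRanges::union(claimed, own)
    if (length(own)) {
      segments[[cl]] <- tibble::tibble(start = IRanges::start(own) - 1L,
                                       end = IRanges::end(own), class = cl)
    }
  }
  rest <- IRanges::setdiff(full, claimed)
  if (length(rest)) {
    segments$OTHER <- tibble::tibble(start = IRanges::start(rest) - 1L,
                                     end = IRanges::end(rest), class = "OTHER")
  }
  seg <- dplyr::arrange(dplyr::bind_rows(segments), .data$start)
  if (min_segment > 1L && nrow(seg) > 1) {
    repeat {
      w <- seg$end - seg$start
      i <- which(w < min_segment)
      if (length(i) == 0) break
      i <- i[which.min(w[i])]
      j <- if (i == 1) 2L else if (i == nrow(seg)) i - 1L else {
        if (w[i - 1] >= w[i + 1]) i - 1L else i + 1L
      }
      seg$class[i] <- seg$class[j]
      seg <- collapse_runs(seg)
    }
  } else {
    seg <- collapse_runs(seg)
  }
  seg <- tibble::tibble(seq_id = focal$id[1], seg)
  lv <- c("CONSERVED", "PLASTID_LIKE", "REPETITIVE", "SPECIFIC", "OTHER")
  totals <- vapply(lv, function(cl) {
    sum(seg$end[seg$class == cl] - seg$start[seg$class == cl])
  }, numeric(1))
  structure(list(genome_id = focal$id[1], length = L, segments = seg,
                 totals = totals, proportions = totals / L,
                 intervals = list(plastid_like = pl, repetitive = rp,
                                  conserved = cv, specific = sp),
                 precedence = names(classes)),
            class = "partition_result")
}

# merge touching runs of equal class labels
collapse_runs <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  keep <- c(TRUE, !(seg$class[-1] == seg$class[-nrow(seg)] &
                      seg$start[-1] == seg$end[-nrow(seg)]))
  seg$.grp <- cumsum(keep)
  out <- dplyr::summarise(dplyr::group_by(seg, .data$.grp),
                          start = min(.data$start), end = max(.data$end),
                          class = .data$class[1], .groups = "drop")
  out[, c("start", "end", "class")]
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Mitogenome partition of", x$genome_id,
      sprintf("(%d bp, %d segments)\n", x$length, nrow(x$segments)))
  p <- sprintf("%5.1f%%", 100 * x$proportions)
  cat(paste(sprintf("  %-13s %9d bp %s", names(x$totals), x$totals, p),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @describeIn classify_genome segment table of a partition.
#' @param x a `partition_result`.
#' @param ... unused.
#' @export
tidy.partition_result <- function(x, ...) x$segments

#' @describeIn classify_genome one-row summary (bp and proportion per class).
#' @export
glance.partition_result <- function(x, ...) {
  out <- tibble::tibble(genome_id = x$genome_id, length = x$length)
  for (cl in names(x$totals)) {
    out[[paste0(tolower(cl), "_bp")]] <- unname(x$totals[cl])
    out[[paste0(tolower(cl), "_frac")]] <- unname(x$proportions[cl])
  }
  out
}
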