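#' Build a donor database
#'
#' A donor database stands in for a broad nucleotide search: a set of donor
#' genomes, each labelled with its taxonomic order, used to attribute
#' specific (GSS) segments to their most likely source lineages.
#'
#' @param id,seq,taxon_order vectors of donor ids, sequences and order labels.
#' @param genus,species optional taxon labels.
#' @return A `genome_set` tibble with role "donor" and a `taxon_order` column.
#' @export
donor_db <- function(id, seq, taxon_order, genus = NA_character_,
                     species = NA_character_) {
  if (any(is.na(taxon_order)) || any(!nzchar(taxon_order))) {
    stop("every donor record needs a non-empty taxon_order", call. = FALSE)
  }
  gs <- genome_set(id, seq, genus = genus, species = species,
                   topology = "linear", role = "donor")
  gs$taxon_order <- rep_len(as.character(taxon_order), nrow(gs))
  gs
}

# extract segment sequences from a genome
segment_seqs <- function(genome, segments) {
  substring(genome$seq[1], segments$start + 1L, segments$end)
}

#' Attribute specific segments to donor taxa
#'
#' For each specific (GSS) segment, the best single hit over all donor
#' records decides the attribution (ties broken by bitscore, then alignment
#' length, then donor id, then subject start). Best hits shorter than
#' `donor_hit_min_len` are treated as no hit, giving order "unknown".
#'
#' @param segments tibble of SPECIFIC-class intervals (`seq_id`, `start`,
#'   `end`), e.g. from [specific_intervals()] or [tidy()] of a partition.
#' @param focal one-row `genome_set` the segments live on.
#' @param donors a [donor_db()].
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @return A tibble with one row per segment: coordinates, `length`, `order`
#'   ("unknown" when no qualifying hit), and best-hit statistics.
#' @export
attribute_segments <- function(segments, focal, donors, th = thresholds(),
                               params = alignment_params()) {
  focal <- as_genome(focal)
  if (is.null(donors) || nrow(donors) == 0) {
    stop("donor database is empty", call. = FALSE)
  }
  n <- nrow(segments)
  out <- tibble::tibble(
    segment_id = paste0(segments$seq_id, ":", segments$start, "-", segments$end),
    seq_id = segments$seq_id, start = segments$start, end = segments$end,
    length = segments$end - segments$start,
    order = "unknown", donor_id = NA_character_,
    best_bitscore = NA_real_, best_aln_len = NA_integer_,
    best_identity = NA_real_
  )
  if (n == 0) return(out)
  seqs <- segment_seqs(focal, segments)
  qset <- genome_set(id = out$segment_id, seq = seqs, topology = "linear")
  for (i in seq_len(nrow(donors))) {
    h <- find_hits(qset, donors[i, ], th = th, params = params)
    if (nrow(h) == 0) next
    h <- h[h$aln_len >= th$donor_hit_min_len, , drop = FALSE]
    for (j in seq_len(n)) {
      hj <- h[h$query_id == out$segment_id[j], , drop = FALSE]
      if (nrow(hj) == 0) next
      b <- hj[1, ]  # find_hits is sorted by the tie-break chain
      better <- is.na(out$best_bitscore[j]) ||
        b$bitscore > out$best_bitscore[j] ||
        (b$bitscore == out$best_bitscore[j] && b$aln_len > out$best_aln_len[j]) ||
        (b$bitscore == out$best_bitscore[j] && b$aln_len == out$best_aln_len[j] &&
           donors$id[i] < out$donor_id[j])
      if (better) {
        out$order[j] <- donors$taxon_order[i]
        out$donor_id[j] <- donors$id[i]
        out$best_bitscore[j] <- b$bitscore
        out$best_aln_len[j] <- b$aln_len
        out$best_identity[j] <- b$identity
      }
    }
  }
  out
}

#' Aggregate attributions by donor order
#'
#' Sums segment lengths per order. The `display` flag marks orders whose
#' total exceeds `order_display_min` (the pie-chart rule); "unknown" is
#' always reported and always displayed.
#'
#' @param attributions output of [attribute_segments()].
#' @param th [thresholds()].
#' @return A tibble with `order`, `total_bp`, `n_segments`, `display`.
#' @export
aggregate_by_order <- function(attributions, th = thresholds()) {
  if (nrow(attributions) == 0) {
    return(tibble::tibble(order = character(), total_bp = integer(),
                          n_segments = integer(), display = logical()))
  }
  out <- dplyr::summarise(dplyr::group_by(attributions, .data$order),
                          total_bp = sum(.data$length),
                          n_segments = dplyr::n(), .groups = "drop")
  out$display <- out$total_bp > th$order_display_min | out$order == "unknown"
  dplyr::arrange(out, dplyr::desc(.data$total_bp))
}

#' HGT-like segments
#'
#' Specific segments whose best donor hit is longer than `hgt_like_min_len`
#' (strictly; default >500 bp) — the high-confidence horizontal-transfer
#' candidates.
#'
#' @inheritParams aggregate_by_order
#' @return The qualifying rows of `attributions`.
#' @export
hgt_like <- function(attributions, th = thresholds()) {
  keep <- !is.na(attributions$best_aln_len) &
    attributions$best_aln_len > th$hgt_like_min_len
  attributions[keep, , drop = FALSE]
}

#' Cross-genome coverage matrix of HGT-like segments
#'
#' For each segment and each target genome, the fraction of segment bases
#' covered by at least one qualifying hit (e-value within the ceiling)
#' against that genome — per-base union coverage, so entries lie between 0
#' and 1.
#'
#' @param segments tibble of segments (`seq_id`, `start`, `end`), e.g. from
#'   [hgt_like()].
#' @param focal one-row `genome_set` the segments live on.
#' @param targets `genome_set` of target genomes.
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @return A numeric matrix, rows = segments, columns = target genome ids.
#' @export
coverage_matrix <- function(segments, focal, targets, th = thresholds(),
                            params = alignment_params()) {
  focal <- as_genome(focal)
  if (is.null(targets) || nrow(targets) == 0) {
    stop("at least one target genome is required", call. = FALSE)
  }
  ids <- paste0(segments$seq_id, ":", segments$start, "-", segments$end)
  m <- matrix(0, nrow = nrow(segments), ncol = nrow(targets),
              dimnames = list(ids, targets$id))
  if (nrow(segments) == 0) return(m)
  seqs <- segment_seqs(focal, segments)
  qset <- genome_set(id = ids, seq = seqs, topology = "linear")
  lens <- segments$end - segments$start
  for (i in seq_len(nrow(targets))) {
    h <- find_hits(qset, targets[i, ], th = th, params = params)
    for (j in seq_len(nrow(segments))) {
      hj <- h[h$query_id == ids[j], , drop = FALSE]
      if (nrow(hj) == 0) next
      cov <- reduce_intervals(hj$q_start, hj$q_end)
      m[j, i] <- sum(cov$end - cov$start) / lens[j]
    }
  }
  m
}

#' Summarise a coverage matrix by donor order
#'
#' Optional aggregation: mean per-base coverage of all segments attributed to
#' each order, per target genome.
#'
#' @param mat matrix from [coverage_matrix()].
#' @param attributions output of [attribute_segments()] restricted to the
#'   same segments (rows must correspond).
#' @return A tibble with `order`, one column per target genome.
#' @export
coverage_by_order <- function(mat, attributions) {
  stopifnot(nrow(mat) == nrow(attributions))
  df <- tibble::as_tibble(mat)
  df$order <- attributions$order
  dplyr::summarise(dplyr::group_by(df, .data$order),
                   dplyr::across(dplyr::everything(), mean), .groups = "drop")
}
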