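#' Analysis thresholds
#'
#' Bundles every tunable cutoff used across the pipeline. Defaults follow the
#' conventions of family-scale organelle comparative studies: plastid-derived
#' ("MTPT") regions are called at >90% nucleotide identity against a plastome,
#' dispersed repeats at >95% identity against the genome itself, homology
#' searches use exact 16-mer seeding with an e-value ceiling of 1e-5, donor
#' attributions ignore hits of 100 bp or less, HGT-like calls require best hits
#' longer than 500 bp, donor orders are displayed when their summed length
#' exceeds 5 kb, synteny uses 50-bp fragments as pseudo-genes, and splicing
#' calls read transcriptome depth against low/high bands of 50 and 400 reads.
#'
#' @param word_size exact seed length (bp) for homology search.
#' @param evalue_max e-value ceiling for reported hits.
#' @param plastid_identity_min minimum percent identity (exclusive) for a hit
#'   to count as plastid-like.
#' @param repeat_identity_min minimum percent identity (exclusive) for a
#'   self-hit to count as repetitive.
#' @param donor_hit_min_len minimum alignment length (bp, exclusive) for a
#'   donor best hit to yield an attribution.
#' @param hgt_like_min_len minimum best-hit length (bp, exclusive) for a
#'   segment to be called HGT-like.
#' @param order_display_min minimum summed length (bp, exclusive) for a donor
#'   order to enter the display subset.
#' @param synteny_fragment_len fragment ("pseudo-gene") length in bp.
#' @param cov_low,cov_high read-depth bands (reads) used by the splicing call.
#' @return A list of class `orgamosaic_thresholds`.
#' @export
thresholds <- function(word_size = 16L,
                       evalue_max = 1e-5,
                       plastid_identity_min = 90,
                       repeat_identity_min = 95,
                       donor_hit_min_len = 100L,
                       hgt_like_min_len = 500L,
                       order_display_min = 5000L,
                       synteny_fragment_len = 50L,
                       cov_low = 50,
                       cov_high = 400) {
  th <- list(
    word_size = as.integer(word_size),
    evalue_max = as.numeric(evalue_max),
    plastid_identity_min = as.numeric(plastid_identity_min),
    repeat_identity_min = as.numeric(repeat_identity_min),
    donor_hit_min_len = as.integer(donor_hit_min_len),
    hgt_like_min_len = as.integer(hgt_like_min_len),
    order_display_min = as.integer(order_display_min),
    synteny_fragment_len = as.integer(synteny_fragment_len),
    cov_low = as.numeric(cov_low),
    cov_high = as.numeric(cov_high)
  )
  nums <- unlist(th)
  if (any(!is.finite(nums)) || any(nums <= 0)) {
    stop("all thresholds must be positive and finite", call. = FALSE)
  }
  for (f in c("plastid_identity_min", "repeat_identity_min")) {
    if (th[[f]] > 100) stop(f, " must lie in (0, 100]", call. = FALSE)
  }
  structure(th, class = "orgamosaic_thresholds")
}

#' Read thresholds from a key=value text file
#'
#' Lines of the form `key = value`; `#` starts a comment; unknown keys are an
#' error. Missing keys keep their defaults.
#'
#' @param path file path.
#' @return An `orgamosaic_thresholds` list.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed threshold line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% names(formals(thresholds))) {
      stop("unknown threshold key: ", key, call. = FALSE)
    }
    args[[key]] <- as.numeric(trimws(kv[2]))
  }
  do.call(thresholds, args)
}

#' Alignment scoring parameters
#'
#' Scoring scheme of the native seed-and-extend homology engine; defaults mimic
#' megablast-like behaviour (match +1, mismatch -2, affine gaps where a gap of
#' length g costs `|gap_open| + g * |gap_extend|`). E-values come from
#' Karlin-Altschul statistics with the ungapped nucleotide constants K = 0.71
#' and lambda = 1.37 applied to gapped scores; this is an approximation, and
#' downstream logic only relies on the e-value ceiling, not on exact BLAST
#' agreement.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open,gap_extend affine gap penalties (< 0).
#' @param xdrop x-drop cutoff for ungapped extension.
#' @param band maximum diagonal shift when chaining gapped hits.
#' @param max_chain_gap maximum bridged distance (bp) when chaining.
#' @param K,lambda Karlin-Altschul constants.
#' @return A list of class `orgamosaic_alnparams`.
#' @export
alignment_params <- function(match = 1L, mismatch = -2L,
                             gap_open = -5L, gap_extend = -2L,
                             xdrop = 20L, band = 50L, max_chain_gap = 200L,
                             K = 0.71, lambda = 1.37) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            xdrop > 0, band > 0, max_chain_gap > 0, K > 0, lambda > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop), band = as.integer(band),
                 max_chain_gap = as.integer(max_chain_gap),
                 K = K, lambda = lambda),
            class = "orgamosaic_alnparams")
}
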