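#' @name fission
#' @title Gene-fission analysis of a two-exon mitochondrial gene
#'
#' @description
#' These functions reconstruct what happened to a canonically intact two-exon
#' gene (the ccmFc situation: exon1 + group II cis-splicing intron + exon2)
#' in a target mitogenome where it may have broken into fragments: locating
#' the fragments, measuring coding loss at the breakpoints, characterising
#' the insertion between the intron-side fragments and its plastid-derived
#' content, scanning the new coding extents (downstream stop for the first
#' fragment's gene, upstream start codon for the second gene), checking the
#' intron binding region, and reading cis/trans splicing evidence from
#' transcriptome coverage.
NULL

# region coordinate helpers: the "region" is the reference gene span,
# 0-based, oriented 5'->3' on the gene strand
region_layout <- function(ref, model) {
  ex <- model$exons[[1]]
  if (model$strand == "+") {
    starts <- ex$start - model$start
    ends <- ex$end - model$start
  } else {
    # mirror: 5'->3' of the gene
    starts <- rev(model$end - ex$end)
    ends <- rev(model$end - ex$start)
  }
  seq <- substring(ref$seq[1], model$start + 1L, model$end)
  if (model$strand == "-") seq <- revcomp(seq)
  list(seq = seq, exon_starts = starts, exon_ends = ends,
       length = model$end - model$start)
}

# number of exonic (coding) bases of the region in [a, b)
coding_nt_between <- function(layout, a, b) {
  if (b <= a) return(0L)
  sum(pmax(0L, pmin(b, layout$exon_ends) - pmax(a, layout$exon_starts)))
}

#' Locate the fragments of a reference gene in a target genome
#'
#' Searches the full reference gene region (exons + intron) against the
#' target; co-linear nearby hits are merged, the rest are labelled FR1, FR2,
#' ... in reference-coordinate order. An intact copy yields a single
#' fragment; a gene absent from the target yields zero rows (not an error).
#'
#' @param target one-row `genome_set`.
#' @param ref one-row `genome_set` carrying the intact reference gene.
#' @param model a one-row `gene_models` tibble for the reference gene.
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @param min_fragment_len ignore stray hits shorter than this (bp).
#' @return A tibble with `label`, `q_start`, `q_end` (reference-region
#'   coordinates, 0-based), `t_seq`, `t_start`, `t_end` (target genomic),
#'   `strand`, `identity`, `aln_len`, `gap_opens`.
#' @export
locate_fragments <- function(target, ref, model, th = thresholds(),
                             params = alignment_params(),
                             min_fragment_len = 30L) {
  target <- as_genome(target)
  lay <- region_layout(as_genome(ref), model)
  h <- find_hits(lay$seq, target, th = th, params = params)
  h <- h[h$aln_len >= min_fragment_len & h$s_end > h$s_start, , drop = FALSE]
  if (nrow(h) == 0) {
    return(tibble::tibble(label = character(), q_start = integer(),
                          q_end = integer(), t_seq = character(),
                          t_start = integer(), t_end = integer(),
                          strand = character(), identity = numeric(),
                          aln_len = integer(), gap_opens = integer()))
  }
  h <- h[order(h$q_start), , drop = FALSE]
  tibble::tibble(
    label = paste0("FR", seq_len(nrow(h))),
    q_start = h$q_start, q_end = h$q_end,
    t_seq = h$subject_id, t_start = h$s_start, t_end = h$s_end,
    strand = h$strand, identity = h$identity, aln_len = h$aln_len,
    gap_opens = h$gap_opens
  )
}

#' Infer breakpoint losses
#'
#' The first break separates FR1 from FR2: the coding (exonic) span of the
#' reference lost between them is reported in nucleotides and amino acids
#' (floor of nt/3, frame taken from the reference), together with the
#' reference codon coordinates of the lost span. The second break lies
#' between FR2 and FR3; its loss is reported in nucleotides (0 for a clean
#' intron split). Fragment overlaps up to the seed word size are treated as
#' breakpoint micro-homology and resolved to the leftmost placement; larger
#' overlaps raise a consistency error.
#'
#' @param fragments tibble from [locate_fragments()] (at least two rows).
#' @param ref,model the reference genome and gene model.
#' @param th [thresholds()].
#' @return A list: `break1_lost_nt`, `break1_lost_aa`, `break1_codons`
#'   (first/last reference codon lost, 1-based), `break2_lost_nt`.
#' @export
infer_breakpoints <- function(fragments, ref, model, th = thresholds()) {
  if (nrow(fragments) < 2) {
    stop("breakpoint inference needs at least two fragments", call. = FALSE)
  }
  lay <- region_layout(as_genome(ref), model)
  ov <- fragments$q_end[-nrow(fragments)] - fragments$q_start[-1]
  if (any(ov > th$word_size)) {
    stop("fragments overlap on the reference by more than the word size",
         call. = FALSE)
  }
  f1 <- fragments[1, ]; f2 <- fragments[2, ]
  a <- f1$q_end; b <- max(f1$q_end, f2$q_start)  # leftmost normalisation
  lost_nt <- coding_nt_between(lay, a, b)
  lost_aa <- lost_nt %/% 3L
  codons <- if (lost_nt > 0) {
    first <- coding_nt_between(lay, 0L, a) %/% 3L + 1L
    c(first, first + lost_aa - 1L)
  } else {
    c(NA_integer_, NA_integer_)
  }
  break2 <- if (nrow(fragments) >= 3) {
    max(0L, fragments$q_start[3] - fragments$q_end[2])
  } else {
    NA_integer_
  }
  list(break1_lost_nt = as.integer(lost_nt),
       break1_lost_aa = as.integer(lost_aa),
       break1_codons = codons,
       break2_lost_nt = break2)
}

#' Analyse the FR2-FR3 gap
#'
#' If FR2 and FR3 sit on the same target locus in the same orientation and
#' order, the region between them is an insertion: its length and its
#' plastid-derived content (the >90%-identity plastid-homology rule) are
#' reported. Otherwise — different sequences, different strands, inverted
#' order, or a distance beyond `max_insertion` (separate loci rather than an
#' intronic insertion) — the connection is broken and the fragments are
#' separated.
#'
#' @param target one-row `genome_set`.
#' @param fragments tibble from [locate_fragments()] with FR2 and FR3.
#' @param plastomes optional `genome_set` of plastomes for the
#'   plastid-content call.
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @param max_insertion largest gap (bp) still interpreted as an insertion
#'   between adjacent fragments.
#' @return A list: `status` ("adjacent"/"separated"), `insertion_len`,
#'   `plastid_bp` (NA when no plastomes are given or status is separated).
#' @export
analyze_gap <- function(target, fragments, plastomes = NULL,
                        th = thresholds(), params = alignment_params(),
                        max_insertion = 10000L) {
  target <- as_genome(target)
  fr <- fragments[fragments$label %in% c("FR2", "FR3"), , drop = FALSE]
  if (nrow(fr) < 2) stop("FR2 and FR3 must both be located", call. = FALSE)
  f2 <- fr[fr$label == "FR2", ]; f3 <- fr[fr$label == "FR3", ]
  same_locus <- f2$t_seq == f3$t_seq && f2$strand == f3$strand
  gap <- if (!same_locus) {
    -1L
  } else if (f2$strand == "+") {
    f3$t_start - f2$t_end
  } else {
    f2$t_start - f3$t_end
  }
  if (!same_locus || gap < 0 || gap > max_insertion) {
    return(list(status = "separated", insertion_len = NA_integer_,
                plastid_bp = NA_integer_))
  }
  g0 <- if (f2$strand == "+") f2$t_end else f3$t_end
  plastid_bp <- NA_integer_
  if (!is.null(plastomes) && gap > 0) {
    gap_seq <- substring(target$seq[1], g0 + 1L, g0 + gap)
    pl <- plastid_like_intervals(genome_set("gap", gap_seq, topology = "linear"),
                                 plastomes, th, params)
    plastid_bp <- as.integer(sum(pl$end - pl$start))
  }
  list(status = "adjacent", insertion_len = as.integer(gap),
       plastid_bp = plastid_bp)
}

# gene-oriented substring of the target: n bases downstream of pos
# (for "+" pos is a 0-based offset; downstream means increasing coordinates)
oriented_downstream <- function(seq, pos, strand, n) {
  if (strand == "+") {
    substring(seq, pos + 1L, min(nchar(seq), pos + n))
  } else {
    revcomp(substring(seq, max(1L, pos - n + 1L), pos))
  }
}

oriented_upstream <- function(seq, pos, strand, n) {
  if (strand == "+") {
    substring(seq, max(1L, pos - n + 1L), pos)
  } else {
    revcomp(substring(seq, pos + 1L, min(nchar(seq), pos + n)))
  }
}

is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Scan coding expansions at the fission breaks
#'
#' After fission, the first fragment's gene has lost its stop codon and the
#' second gene its start codon. The scan walks downstream of the FR1 break
#' in the reference reading frame to the first in-frame stop (expansion of
#' the first gene, in codons, stop exclusive), and upstream of the FR2 break
#' to the nearest in-frame ATG with no intervening in-frame stop (expansion
#' of the second gene, ATG inclusive). When `full_expansion_aa` (the
#' expansion seen in non-truncated relatives) is supplied and the downstream
#' stop comes earlier, the first gene is reported as truncated at that
#' position — the nonsense-mutation situation.
#'
#' @param target one-row `genome_set`.
#' @param fragments tibble from [locate_fragments()].
#' @param ref,model reference genome and gene model.
#' @param scan_window maximum scan distance in nt.
#' @param full_expansion_aa optional expected full expansion of the first
#'   gene, in aa.
#' @return A list: `ccmFc1_aa`, `ccmFc2_aa`, `truncated_at` (NA unless a
#'   premature stop shortens the first expansion), `unresolved` flags.
#' @export
scan_expansion <- function(target, fragments, ref, model,
                           scan_window = 3000L, full_expansion_aa = NULL) {
  target <- as_genome(target)
  lay <- region_layout(as_genome(ref), model)
  f1 <- fragments[fragments$label == "FR1", ]
  f2 <- fragments[fragments$label == "FR2", ]
  if (nrow(f1) == 0 || nrow(f2) == 0) {
    stop("FR1 and FR2 must both be located", call. = FALSE)
  }
  ts <- target$seq[1]
  # downstream of FR1's 3' break, in frame
  c1 <- coding_nt_between(lay, 0L, f1$q_end)
  rem1 <- c1 %% 3L
  p1 <- if (f1$strand == "+") f1$t_end else f1$t_start
  down <- oriented_downstream(ts, p1, f1$strand, scan_window + 3L)
  # prepend the partial-codon tail so codon boundaries line up
  tail_nt <- if (rem1 > 0) oriented_upstream(ts, p1, f1$strand, rem1) else ""
  frame1 <- paste0(tail_nt, down)
  n_codons <- nchar(frame1) %/% 3L
  cc1 <- NA_integer_; unresolved1 <- TRUE
  for (k in seq_len(n_codons)) {
    codon <- substring(frame1, 3L * k - 2L, 3L * k)
    if (is_stop(codon)) {
      cc1 <- k - 1L  # codons gained before the stop, stop exclusive
      unresolved1 <- FALSE
      break
    }
  }
  # upstream of FR2's 5' break: nearest in-frame ATG, no intervening stop
  c2 <- coding_nt_between(lay, 0L, f2$q_start)
  rem2 <- c2 %% 3L
  p2 <- if (f2$strand == "+") f2$t_start else f2$t_end
  up <- oriented_upstream(ts, p2, f2$strand, scan_window + 3L)
  if (rem2 > 0) up <- substring(up, 1L, nchar(up) - rem2)
  cc2 <- NA_integer_; unresolved2 <- TRUE
  n_up <- nchar(up) %/% 3L
  for (k in seq_len(n_up)) {
    codon <- substring(up, nchar(up) - 3L * k + 1L, nchar(up) - 3L * k + 3L)
    if (is_stop(codon)) break
    if (codon == "ATG") { cc2 <- k; unresolved2 <- FALSE; break }
  }
  truncated_at <- NA_integer_
  if (!is.null(full_expansion_aa) && !unresolved1 && !is.na(cc1) &&
      cc1 < full_expansion_aa) {
    truncated_at <- cc1
  }
  list(ccmFc1_aa = cc1, ccmFc2_aa = cc2, truncated_at = truncated_at,
       unresolved = c(ccmFc1 = unresolved1, ccmFc2 = unresolved2))
}

#' Classify a gene copy as intact, pseudo or missing
#'
#' A copy with no protein-level homology to the reference is missing; one
#' with a premature internal stop codon, a non-triplet length change
#' (frameshift) or a truncation beyond `max_truncation` of the reference
#' length is a pseudogene; anything else is intact.
#'
#' @param target_gene_seq nucleotide sequence of the candidate gene copy
#'   (CDS orientation; empty string means absent).
#' @param ref_protein reference protein sequence (no trailing stop).
#' @param max_truncation tolerated fractional length loss (default 0.2).
#' @param min_coverage minimum fraction of the reference protein that must
#'   align locally for the copy to count as present.
#' @return "intact", "pseudo" or "missing".
#' @export
classify_gene_status <- function(target_gene_seq, ref_protein,
                                 max_truncation = 0.2, min_coverage = 0.3) {
  if (is.na(target_gene_seq) || nchar(target_gene_seq) < 3) return("missing")
  trim <- nchar(target_gene_seq) - nchar(target_gene_seq) %% 3L
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substring(target_gene_seq, 1, trim)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  core <- sub("\\*$", "", prot)  # a terminal stop is fine
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("\\*", "X", prot)),
    Biostrings::AAString(ref_protein),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 2)
  cov <- (Biostrings::end(Biostrings::subject(pa)) -
            Biostrings::start(Biostrings::subject(pa)) + 1) / nchar(ref_protein)
  if (Biostrings::score(pa) <= 0 || cov < min_coverage) return("missing")
  if (nchar(target_gene_seq) %% 3L != 0L) return("pseudo")     # frameshift
  if (grepl("\\*", core)) return("pseudo")                     # premature stop
  if (nchar(core) < (1 - max_truncation) * nchar(ref_protein)) return("pseudo")
  "intact"
}

#' Call cis/trans splicing from transcriptome coverage
#'
#' Compares the median read depth over the exonic bases of FR2 and FR3 (E)
#' with the median over the intron-side window immediately downstream of
#' FR2's 3' end (I), i.e. the region that would connect FR2 to FR3 in an
#' unbroken cis-spliced precursor. The call is "trans" when the connecting
#' region is essentially silent while the exons are highly expressed
#' (I < `cov_low` and E > `cov_high`), "cis" when the connecting region is
#' expressed at a comparable level (I >= 0.5 E), and "ambiguous" otherwise.
#'
#' @param coverage integer vector of per-base depth over the target genome.
#' @param fragments tibble from [locate_fragments()].
#' @param ref,model reference genome and gene model.
#' @param th [thresholds()] (supplies `cov_low`, `cov_high`).
#' @param window intron-side window width in bp.
#' @param cis_ratio I/E ratio above which the call is cis.
#' @return "cis", "trans" or "ambiguous".
#' @export
splicing_call <- function(coverage, fragments, ref, model, th = thresholds(),
                          window = 200L, cis_ratio = 0.5) {
  lay <- region_layout(as_genome(ref), model)
  fr <- fragments[fragments$label %in% c("FR2", "FR3"), , drop = FALSE]
  if (nrow(fr) == 0) stop("FR2/FR3 fragments required", call. = FALSE)
  exonic <- integer()
  for (i in seq_len(nrow(fr))) {
    f <- fr[i, ]
    for (j in seq_along(lay$exon_starts)) {
      a <- max(f$q_start, lay$exon_starts[j])
      b <- min(f$q_end, lay$exon_ends[j])
      if (b <= a) next
      if (f$strand == "+") {
        exonic <- c(exonic, (f$t_start + (a - f$q_start)):(f$t_start + (b - f$q_start) - 1L))
      } else {
        exonic <- c(exonic, (f$t_end - (b - f$q_start)):(f$t_end - (a - f$q_start) - 1L))
      }
    }
  }
  exonic <- exonic[exonic >= 0 & exonic < length(coverage)]
  if (length(exonic) == 0 || all(coverage[exonic + 1L] == 0)) {
    warning("no exonic coverage over FR2/FR3; call is ambiguous")
    return("ambiguous")
  }
  E <- stats::median(coverage[exonic + 1L])
  f2 <- fr[fr$label == "FR2", ]
  iwin <- if (f2$strand == "+") {
    (f2$t_end):(min(length(coverage), f2$t_end + window) - 1L)
  } else {
    (max(0L, f2$t_start - window)):(f2$t_start - 1L)
  }
  I <- stats::median(coverage[iwin + 1L])
  if (E <= th$cov_low) return("ambiguous")  # no signal to compare against
  if (I < th$cov_low && E > th$cov_high) return("trans")
  if (I >= cis_ratio * E) return("cis")
  "ambiguous"
}

#' Check the intron binding region
#'
#' Aligns the reference intron binding window (the ~48-nt segment recognised
#' by the nuclear splicing factor) to the target. A full-length match with
#' no indel is preserved; an insertion interrupting the window is reported
#' with its length; a window absent from the target is disrupted with
#' unknown insertion length.
#'
#' @param target one-row `genome_set`.
#' @param ref,model reference genome and gene model (the model must carry
#'   `binding_start`/`binding_end`).
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @param word_size seed length for the short-window search.
#' @return A list: `status` ("preserved"/"disrupted"), `matched_len`,
#'   `insertion_len` (NA when the window is absent).
#' @export
binding_region_check <- function(target, ref, model, th = thresholds(),
                                 params = alignment_params(), word_size = 12L) {
  target <- as_genome(target); ref <- as_genome(ref)
  if (is.na(model$binding_start) || is.na(model$binding_end)) {
    stop("gene model has no binding region", call. = FALSE)
  }
  wseq <- substring(ref$seq[1], model$binding_start + 1L, model$binding_end)
  if (model$strand == "-") wseq <- revcomp(wseq)
  wlen <- nchar(wseq)
  h <- find_hits(wseq, target, th = th, params = params, word_size = word_size)
  h <- h[h$s_end > h$s_start, , drop = FALSE]
  if (nrow(h) == 0) {
    return(list(status = "disrupted", matched_len = 0L,
                insertion_len = NA_integer_))
  }
  b <- h[1, ]
  q_cov <- b$q_end - b$q_start
  t_span <- b$s_end - b$s_start
  if (q_cov == wlen && t_span == q_cov && b$gap_opens == 0) {
    return(list(status = "preserved", matched_len = as.integer(wlen),
                insertion_len = 0L))
  }
  if (q_cov >= wlen - 2L && t_span > q_cov) {
    return(list(status = "disrupted", matched_len = as.integer(q_cov),
                insertion_len = as.integer(t_span - q_cov)))
  }
  # two unchained partial matches flanking a long insert
  if (nrow(h) >= 2) {
    h2 <- h[order(h$q_start), , drop = FALSE]
    a <- h2[1, ]; z <- h2[nrow(h2), ]
    if (a$strand == z$strand && z$q_start >= a$q_end - 2L) {
      tgap <- if (a$strand == "+") z$s_start - a$s_end else a$s_start - z$s_end
      qgap <- z$q_start - a$q_end
      if (tgap > qgap) {
        return(list(status = "disrupted",
                    matched_len = as.integer((a$q_end - a$q_start) +
                                               (z$q_end - z$q_start)),
                    insertion_len = as.integer(tgap - max(0L, qgap))))
      }
    }
  }
  list(status = "disrupted", matched_len = as.integer(q_cov),
       insertion_len = NA_integer_)
}

#' Full fission analysis of a target genome
#'
#' Orchestrates [locate_fragments()], [infer_breakpoints()],
#' [analyze_gap()], [scan_expansion()], [binding_region_check()] and,
#' when coverage is supplied, [splicing_call()] into one report.
#'
#' @param target one-row `genome_set`.
#' @param ref,model reference genome and gene model.
#' @param plastomes optional `genome_set` for the plastid-content call.
#' @param coverage optional per-base depth vector for the splicing call.
#' @param th [thresholds()].
#' @param params [alignment_params()].
#' @param full_expansion_aa passed to [scan_expansion()].
#' @return A `fission_report` object (list). Supports [tidy()] (fragment
#'   table) and [glance()] (one-row summary).
#' @export
analyze_fission <- function(target, ref, model, plastomes = NULL,
                            coverage = NULL, th = thresholds(),
                            params = alignment_params(),
                            full_expansion_aa = NULL) {
  target <- as_genome(target)
  frags <- locate_fragments(target, ref, model, th, params)
  rep <- list(target_id = target$id[1], n_fragments = nrow(frags),
              fragments = frags)
  if (nrow(frags) >= 2) {
    rep$breakpoints <- infer_breakpoints(frags, ref, model, th)
  }
  if (all(c("FR2", "FR3") %in% frags$label)) {
    rep$fr2_fr3_gap <- analyze_gap(target, frags, plastomes, th, params)
  }
  if (all(c("FR1", "FR2") %in% frags$label)) {
    rep$expansion <- scan_expansion(target, frags, ref, model,
                                    full_expansion_aa = full_expansion_aa)
  }
  if (!is.na(model$binding_start)) {
    rep$binding_region <- binding_region_check(target, ref, model, th, params)
  }
  if (!is.null(coverage) && nrow(frags) >= 2) {
    rep$splicing <- splicing_call(coverage, frags, ref, model, th)
  }
  structure(rep, class = "fission_report")
}

#' @export
print.fission_report <- function(x, ...) {
  cat("Fission report for", x$target_id, "-", x$n_fragments, "fragment(s)\n")
  if (!is.null(x$breakpoints)) {
    b <- x$breakpoints
    cat(sprintf("  break 1: %d aa (%d nt) of coding sequence lost",
                b$break1_lost_aa, b$break1_lost_nt))
    if (!is.na(b$break1_codons[1])) {
      cat(sprintf(" (ref codons %d-%d)", b$break1_codons[1], b$break1_codons[2]))
    }
    cat("\n")
    if (!is.na(b$break2_lost_nt)) {
      cat(sprintf("  break 2: %d nt lost within the intron\n", b$break2_lost_nt))
    }
  }
  if (!is.null(x$fr2_fr3_gap)) {
    g <- x$fr2_fr3_gap
    if (g$status == "adjacent") {
      cat(sprintf("  FR2-FR3: adjacent, %d bp insertion (%s bp plastid-derived)\n",
                  g$insertion_len,
                  ifelse(is.na(g$plastid_bp), "?", g$plastid_bp)))
    } else {
      cat("  FR2-FR3: separated (connection broken)\n")
    }
  }
  if (!is.null(x$expansion)) {
    e <- x$expansion
    cat(sprintf("  expansions: gene1 +%s aa%s, gene2 +%s aa\n",
                ifelse(is.na(e$ccmFc1_aa), "?", e$ccmFc1_aa),
                ifelse(is.na(e$truncated_at), "",
                       sprintf(" (truncated at +%d)", e$truncated_at)),
                ifelse(is.na(e$ccmFc2_aa), "?", e$ccmFc2_aa)))
  }
  if (!is.null(x$binding_region)) {
    b <- x$binding_region
    cat(sprintf("  binding region: %s (matched %d nt%s)\n", b$status,
                b$matched_len,
                ifelse(is.na(b$insertion_len) | b$insertion_len == 0, "",
                       sprintf(", %d bp insertion", b$insertion_len))))
  }
  if (!is.null(x$splicing)) cat("  splicing call:", x$splicing, "\n")
  invisible(x)
}

#' @describeIn analyze_fission fragment table of a fission report.
#' @param x a `fission_report`.
#' @param ... unused.
#' @export
tidy.fission_report <- function(x, ...) x$fragments

#' @describeIn analyze_fission one-row summary of a fission report.
#' @export
glance.fission_report <- function(x, ...) {
  tibble::tibble(
    target_id = x$target_id,
    n_fragments = x$n_fragments,
    break1_lost_aa = x$breakpoints$break1_lost_aa %||% NA_integer_,
    break2_lost_nt = x$breakpoints$break2_lost_nt %||% NA_integer_,
    gap_status = x$fr2_fr3_gap$status %||% NA_character_,
    insertion_len = x$fr2_fr3_gap$insertion_len %||% NA_integer_,
    plastid_bp = x$fr2_fr3_gap$plastid_bp %||% NA_integer_,
    expansion1_aa = x$expansion$ccmFc1_aa %||% NA_integer_,
    expansion2_aa = x$expansion$ccmFc2_aa %||% NA_integer_,
    truncated_at = x$expansion$truncated_at %||% NA_integer_,
    binding_status = x$binding_region$status %||% NA_character_,
    splicing = x$splicing %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
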