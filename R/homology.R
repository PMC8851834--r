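#' Local homology search between two genomes
#'
#' Native seed-and-extend nucleotide search: exact `word_size`-mer seeding on
#' both strands (words containing N never seed), ungapped x-drop extension,
#' then diagonal-banded chaining of co-linear HSPs with affine gap costs.
#' Hits above the e-value ceiling are discarded and the rest sorted by
#' bitscore (ties: alignment length, then subject start). For a circular
#' subject the search runs against the doubled sequence and hits are
#' deduplicated back to the original frame; a hit crossing the origin is
#' reported with `s_end < s_start` (modular interval).
#'
#' @param query a one-row `genome_set`, a multi-row `genome_set` (each row is
#'   searched), or a bare DNA string.
#' @param subject a one-row `genome_set` or DNA string.
#' @param th an [thresholds()] object (supplies `word_size`, `evalue_max`).
#' @param params an [alignment_params()] object.
#' @param word_size override for the seed length.
#' @param both_strands search the reverse complement of the query as well.
#' @return A tibble with columns `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open), `strand`, `identity`, `aln_len`,
#'   `mismatches`, `gap_opens`, `raw_score`, `bitscore`, `evalue`.
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
#' find_hits(substr(s, 101, 200), s)
#' @export
find_hits <- function(query, subject, th = thresholds(),
                      params = alignment_params(),
                      word_size = th$word_size, both_strands = TRUE) {
  q <- if (is.data.frame(query)) query else as_genome(query, "query")
  s <- as_genome(subject, "subject")
  L <- s$length[1]
  sseq <- s$seq[1]
  circular <- identical(s$topology[1], "circular")
  if (circular) sseq <- paste0(sseq, s$seq[1])
  df <- .find_hits_cpp(q$seq, sseq,
                       as.integer(word_size), params$match, params$mismatch,
                       params$gap_open, params$gap_extend, params$xdrop,
                       th$evalue_max, params$K, params$lambda,
                       params$band, params$max_chain_gap, both_strands)
  out <- tibble::as_tibble(df)
  out$query_id <- q$id[out$query_idx]
  out$subject_id <- s$id[1]
  out$query_idx <- NULL
  if (circular) {
    out <- out[out$s_start < L, , drop = FALSE]
    # a hit is redundant if its +L image lies inside another hit of the same
    # query and strand (the origin-crossing alignment already covers it)
    if (nrow(out) > 1) {
      drop <- logical(nrow(out))
      for (i in seq_len(nrow(out))) {
        js <- which(!drop & out$strand == out$strand[i] &
                      out$query_id == out$query_id[i])
        for (j in setdiff(js, i)) {
          if (out$q_start[i] >= out$q_start[j] &&
              out$q_end[i] <= out$q_end[j] &&
              out$s_start[i] + L >= out$s_start[j] &&
              out$s_end[i] + L <= out$s_end[j]) {
            drop[i] <- TRUE
            break
          }
        }
      }
      out <- out[!drop, , drop = FALSE]
    }
    wrap <- out$s_end > L
    out$s_end[wrap] <- out$s_end[wrap] - L
  }
  out <- out[order(-out$bitscore, -out$aln_len, out$subject_id, out$s_start), ,
             drop = FALSE]
  dplyr::relocate(out, "query_id", "subject_id")
}

#' Self homology (dispersed and inverted repeats)
#'
#' Runs [find_hits()] of a genome against itself, removes the trivial
#' full-length self-diagonal, and reports each repeat pair once (canonical
#' order `q_start <= s_start`).
#'
#' @inheritParams find_hits
#' @param genome a one-row `genome_set` or DNA string.
#' @return A hits tibble (see [find_hits()]).
#' @export
self_hits <- function(genome, th = thresholds(), params = alignment_params(),
                      word_size = th$word_size) {
  g <- as_genome(genome)
  h <- find_hits(g, g, th = th, params = params, word_size = word_size)
  trivial <- h$strand == "+" & h$q_start == h$s_start & h$q_end == h$s_end
  h <- h[!trivial & h$q_start <= h$s_start, , drop = FALSE]
  h
}

#' Smith-Waterman oracle
#'
#' Full optimal local alignment (dynamic programming via
#' `Biostrings::pairwiseAlignment`) under the same scoring scheme as the
#' seed-and-extend engine; used as an independent reference in tests and for
#' small-scale verification. N never matches anything (including N).
#'
#' @param query,subject DNA strings.
#' @param params an [alignment_params()] object.
#' @param max_cells refuse instances larger than this many DP cells.
#' @return A list with `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open), `identity` and `aln_len`; score 0 and empty
#'   intervals when no positive-scoring alignment exists.
#' @export
sw_oracle <- function(query, subject, params = alignment_params(),
                      max_cells = 4e6) {
  if (as.numeric(nchar(query)) * nchar(subject) > max_cells) {
    stop("sw_oracle size guard exceeded (", nchar(query), " x ",
         nchar(subject), " cells)", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(params$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- params$match
  mat["N", "N"] <- params$mismatch  # N never matches, not even itself
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, q_start = 0L, q_end = 0L, s_start = 0L,
                s_end = 0L, identity = NA_real_, aln_len = 0L))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cols <- strsplit(ap, "")[[1]]
  scols <- strsplit(as_, "")[[1]]
  matches <- sum(cols == scols & cols != "-" & cols != "N")
  list(score = sc,
       q_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       q_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(pa)),
       identity = 100 * matches / length(cols),
       aln_len = length(cols))
}

# union of (start, end) 0-based half-open intervals, bridging gaps < max_gap
reduce_intervals <- function(start, end, max_gap = 0L) {
  if (length(start) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  ir <- IRanges::IRanges(start = start + 1L, end = end)
  r <- IRanges::reduce(ir, min.gapwidth = max(1L, as.integer(max_gap)))
  tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' Merge hit intervals into a disjoint union
#'
#' Takes the query- or subject-side intervals of a hit table
#' (strand-agnostic), bridges gaps smaller than `max_gap`, and returns a
#' sorted disjoint union.
#'
#' @param hits a hits tibble from [find_hits()].
#' @param side "query" or "subject".
#' @param max_gap adjacent intervals separated by fewer than this many bases
#'   are merged.
#' @param seq_length length of the underlying sequence; required to resolve
#'   origin-crossing subject hits of a circular genome.
#' @return A tibble with `seq_id`, `start`, `end`.
#' @export
merge_hit_intervals <- function(hits, side = c("query", "subject"),
                                max_gap = 0L, seq_length = NULL) {
  side <- match.arg(side)
  idc <- if (side == "query") "query_id" else "subject_id"
  sc <- if (side == "query") "q_start" else "s_start"
  ec <- if (side == "query") "q_end" else "s_end"
  if (nrow(hits) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer()))
  }
  ids <- unique(hits[[idc]])
  if (length(ids) != 1) {
    stop("hits span multiple ", side, " sequences: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  start <- hits[[sc]]
  end <- hits[[ec]]
  wrap <- end < start
  if (any(wrap)) {
    if (is.null(seq_length)) {
      stop("origin-crossing hits present; supply seq_length", call. = FALSE)
    }
    start <- c(start[!wrap], start[wrap], rep(0L, sum(wrap)))
    end <- c(end[!wrap], rep(as.integer(seq_length), sum(wrap)), end[wrap])
  }
  r <- reduce_intervals(start, end, max_gap)
  tibble::tibble(seq_id = ids, start = r$start, end = r$end)
}
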