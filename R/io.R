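#' Write labelled intervals as BED
#'
#' BED is 0-based half-open, matching the internal convention; the class label
#' goes in column 4. An empty interval table produces an empty file.
#'
#' @param segments tibble with columns `seq_id`, `start`, `end` and a label
#'   column (`label` or `class`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lab <- if ("label" %in% names(segments)) segments$label else segments$class
  writeLines(paste(segments$seq_id, segments$start, segments$end, lab,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a BED file of labelled intervals
#'
#' @param path BED file (0-based half-open, label in column 4).
#' @return A tibble with `seq_id`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), label = character()))
  }
  f <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(seq_id = as.character(f[[1]]), start = as.integer(f[[2]]),
                 end = as.integer(f[[3]]),
                 label = if (ncol(f) >= 4) as.character(f[[4]]) else NA_character_)
}

#' Write hits in the 12-column tabular dialect
#'
#' Columns: query, subject, %identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore. On-disk coordinates
#' are 1-based inclusive; minus-strand subject hits have sstart > send.
#'
#' @param hits a hits tibble as returned by [find_hits()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_hits <- function(hits, path) {
  if (nrow(hits) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  send <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  writeLines(paste(hits$query_id, hits$subject_id,
                   sprintf("%.3f", hits$identity), hits$aln_len,
                   hits$mismatches, hits$gap_opens,
                   hits$q_start + 1L, hits$q_end, sstart, send,
                   format(hits$evalue, digits = 3, scientific = TRUE),
                   sprintf("%.1f", hits$bitscore), sep = "\t"), path)
  invisible(path)
}

#' Read a 12-column hits table
#'
#' @param path hits TSV as written by [write_tsv_hits()] (or BLASTN outfmt 6).
#' @return A hits tibble in internal 0-based half-open coordinates with an
#'   explicit `strand` column.
#' @export
read_tsv_hits <- function(path) {
  empty <- tibble::tibble(query_id = character(), subject_id = character(),
                          q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          strand = character(), identity = numeric(),
                          aln_len = integer(), mismatches = integer(),
                          gap_opens = integer(), bitscore = numeric(),
                          evalue = numeric())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  f <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  minus <- f[[9]] > f[[10]]
  tibble::tibble(
    query_id = as.character(f[[1]]), subject_id = as.character(f[[2]]),
    q_start = as.integer(f[[7]] - 1L), q_end = as.integer(f[[8]]),
    s_start = as.integer(ifelse(minus, f[[10]], f[[9]]) - 1L),
    s_end = as.integer(ifelse(minus, f[[9]], f[[10]])),
    strand = ifelse(minus, "-", "+"),
    identity = f[[3]], aln_len = as.integer(f[[4]]),
    mismatches = as.integer(f[[5]]), gap_opens = as.integer(f[[6]]),
    bitscore = f[[12]], evalue = f[[11]]
  )
}

#' Write an analysis report as JSON
#'
#' Keys keep their list order, so reports are byte-stable across runs.
#'
#' @param report a named list (e.g. a fission report or partition summary).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a per-base coverage profile
#'
#' Wiggle-like two-column TSV (`position<TAB>depth`, positions 1-based);
#' positions absent from the file get depth 0.
#'
#' @param path TSV file.
#' @param genome_length total length of the profiled sequence; defaults to the
#'   largest position present.
#' @return An integer vector of per-base depths (length `genome_length`).
#' @export
read_coverage_tsv <- function(path, genome_length = NULL) {
  f <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  pos <- as.integer(f[[1]])
  if (is.null(genome_length)) genome_length <- max(pos)
  depth <- integer(genome_length)
  depth[pos] <- as.integer(f[[2]])
  depth
}

#' Write a per-base coverage profile
#'
#' @param depth integer vector of per-base depths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(depth, path) {
  writeLines(paste(seq_along(depth), depth, sep = "\t"), path)
  invisible(path)
}
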