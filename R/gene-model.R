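#' Construct a gene model
#'
#' Gene models are one-row-per-gene tibbles with exon and intron list-columns.
#' Coordinates are 0-based half-open on the genome; exons are ordered 5' to 3'
#' on the gene strand, and introns are derived as the inter-exon gaps. An
#' optional binding-region interval (e.g. the ~48-nt group II intron segment
#' recognised by the nuclear splicing factor WTF9) can be recorded inside the
#' intron.
#'
#' @param gene_id gene identifier.
#' @param seq_id identifier of the genome the model lives on.
#' @param exon_starts,exon_ends integer vectors, 0-based half-open, given in
#'   genomic (left-to-right) order.
#' @param strand "+" or "-".
#' @param code NCBI translation table id (plant mitochondria use the standard
#'   code, table 1).
#' @param binding_start,binding_end optional interval inside the intron.
#' @param check_cds enforce that summed exon length is divisible by 3 (true
#'   for an intact reference gene).
#' @return A one-row tibble of class `gene_models`.
#' @export
gene_model <- function(gene_id, seq_id, exon_starts, exon_ends, strand = "+",
                       code = 1L, binding_start = NA_integer_,
                       binding_end = NA_integer_, check_cds = TRUE) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1,
            strand %in% c("+", "-"))
  ord <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[ord])
  exon_ends <- as.integer(exon_ends[ord])
  if (any(exon_ends <= exon_starts)) stop("empty exon", call. = FALSE)
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] < exon_ends[-length(exon_ends)])) {
    stop("overlapping exons in gene ", gene_id, call. = FALSE)
  }
  if (check_cds && sum(exon_ends - exon_starts) %% 3L != 0L) {
    stop("summed exon length of ", gene_id, " is not divisible by 3",
         call. = FALSE)
  }
  n <- length(exon_starts)
  introns <- if (n > 1) {
    tibble::tibble(start = exon_ends[-n], end = exon_starts[-1])
  } else {
    tibble::tibble(start = integer(), end = integer())
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    seq_id = seq_id,
    strand = strand,
    start = exon_starts[1],
    end = exon_ends[n],
    code = as.integer(code),
    binding_start = as.integer(binding_start),
    binding_end = as.integer(binding_end),
    exons = list(tibble::tibble(start = exon_starts, end = exon_ends)),
    introns = list(introns)
  )
  class(out) <- unique(c("gene_models", class(out)))
  out
}

#' Read gene models from GFF3
#'
#' Understands `gene` and `exon` features; GFF3 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention, and introns are
#' derived as inter-exon gaps.
#'
#' @param path GFF3 file.
#' @param genome optional one-row `genome_set`; when given, exons outside the
#'   genome bounds raise an error.
#' @return A `gene_models` tibble, one row per gene.
#' @export
read_gff3 <- function(path, genome = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop("no features in ", path, call. = FALSE)
  f <- utils::read.table(text = lines, sep = "\t", quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"))
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    ifelse(lengths(m) > 0, sub(paste0("^;?", key, "="), "", unlist(m)), NA)
  }
  genes <- f[f$type == "gene", , drop = FALSE]
  exons <- f[f$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path, call. = FALSE)
  genes$gene_id <- attr_val(genes$attributes, "ID")
  exons$parent <- attr_val(exons$attributes, "Parent")
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[!is.na(exons$parent) & exons$parent == g$gene_id, , drop = FALSE]
    if (nrow(ex) == 0) {
      ex <- g  # intronless gene given without explicit exon rows
    }
    if (!is.null(genome)) {
      if (any(ex$start < 1) || any(ex$end > genome$length[1])) {
        stop("exon of ", g$gene_id, " outside genome bounds", call. = FALSE)
      }
    }
    gene_model(g$gene_id, g$seqid,
               exon_starts = ex$start - 1L, exon_ends = ex$end,
               strand = g$strand, check_cds = FALSE)
  })
  out <- dplyr::bind_rows(models)
  class(out) <- unique(c("gene_models", class(out)))
  out
}

#' Write gene models to GFF3
#'
#' @param models a `gene_models` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    lines <- c(lines,
               paste(m$seq_id, "orgamosaic", "gene", m$start + 1L, m$end,
                     ".", m$strand, ".", paste0("ID=", m$gene_id), sep = "\t"))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
                 paste(m$seq_id, "orgamosaic", "exon", ex$start[j] + 1L,
                       ex$end[j], ".", m$strand, ".",
                       paste0("ID=", m$gene_id, ".exon", j,
                              ";Parent=", m$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
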