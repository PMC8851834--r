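#' Build a genome set
#'
#' A genome set is a tibble with one row per sequence and columns `id`,
#' `genus`, `species`, `topology` ("circular" or "linear"), `role`
#' ("mitogenome", "plastome" or "donor"), `length` and `seq`. Sequences are
#' uppercase DNA over A/C/G/T/N; circular topology means coordinate arithmetic
#' is modular and homology searches use the doubled-sequence device.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of DNA sequences.
#' @param genus,species taxon labels (may be `NA`).
#' @param topology "circular" (default) or "linear", recycled.
#' @param role "mitogenome", "plastome" or "donor", recycled.
#' @return A tibble of class `genome_set`.
#' @examples
#' genome_set(id = "g1", seq = "ACGTACGT", genus = "Ipomoea")
#' @export
genome_set <- function(id, seq, genus = NA_character_, species = NA_character_,
                       topology = "circular", role = "mitogenome") {
  seq <- toupper(seq)
  gs <- tibble::tibble(
    id = as.character(id),
    genus = rep_len(as.character(genus), length(id)),
    species = rep_len(as.character(species), length(id)),
    topology = rep_len(as.character(topology), length(id)),
    role = rep_len(as.character(role), length(id)),
    length = nchar(seq),
    seq = as.character(seq)
  )
  validate_genome_set(gs)
}

validate_genome_set <- function(gs) {
  if (anyDuplicated(gs$id)) {
    stop("duplicate genome ids: ",
         paste(unique(gs$id[duplicated(gs$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(gs$seq))) stop("empty sequence not allowed", call. = FALSE)
  if (!all(gs$topology %in% c("circular", "linear"))) {
    stop("topology must be 'circular' or 'linear'", call. = FALSE)
  }
  if (!all(gs$role %in% c("mitogenome", "plastome", "donor"))) {
    stop("role must be one of mitogenome/plastome/donor", call. = FALSE)
  }
  for (i in seq_len(nrow(gs))) {
    bad <- regexpr("[^ACGTN]", gs$seq[i])
    if (bad > 0) {
      stop(sprintf("invalid character '%s' in record '%s' at position %d",
                   substr(gs$seq[i], bad, bad), gs$id[i], bad), call. = FALSE)
    }
  }
  gs$length <- nchar(gs$seq)
  class(gs) <- unique(c("genome_set", class(gs)))
  gs
}

#' Read genomes from FASTA
#'
#' Header tokens after the identifier may carry `genus=`, `species=`,
#' `topology=` and `role=` key=value annotations. Sequences are uppercased;
#' characters outside A/C/G/T/N are rejected with the offending record and
#' position named.
#'
#' @param path FASTA file.
#' @param role default role for records without a `role=` token.
#' @param topology default topology for records without a `topology=` token.
#' @return A `genome_set` tibble, record order preserved.
#' @export
read_fasta <- function(path, role = "mitogenome", topology = "circular") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  get_kv <- function(header, key, default) {
    m <- regmatches(header, regexpr(paste0(key, "=\\S+"), header))
    if (length(m) == 0) return(default)
    sub(paste0(key, "="), "", m)
  }
  genome_set(
    id = ids,
    seq = toupper(as.character(ss)),
    genus = vapply(headers, get_kv, "", key = "genus", default = NA_character_),
    species = vapply(headers, get_kv, "", key = "species", default = NA_character_),
    topology = vapply(headers, get_kv, "", key = "topology", default = topology),
    role = vapply(headers, get_kv, "", key = "role", default = role)
  )
}

#' Write a genome set to FASTA
#'
#' Taxon and topology annotations are stored as key=value header tokens so
#' that `read_fasta()` round-trips them.
#'
#' @param gs a `genome_set` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(gs, path) {
  hdr <- gs$id
  add <- function(hdr, key, val) {
    keep <- !is.na(val)
    hdr[keep] <- paste0(hdr[keep], " ", key, "=", val[keep])
    hdr
  }
  hdr <- add(hdr, "genus", gs$genus)
  hdr <- add(hdr, "species", gs$species)
  hdr <- add(hdr, "topology", gs$topology)
  hdr <- add(hdr, "role", gs$role)
  ss <- Biostrings::DNAStringSet(gs$seq)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement
#'
#' @param seq character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# resolve a genome argument: one-row genome_set, or a bare character sequence
as_genome <- function(x, id = "seq") {
  if (is.character(x) && length(x) == 1 && !grepl("[^ACGTNacgtn]", x)) {
    return(genome_set(id = id, seq = x, topology = "linear"))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("expected a single genome (one-row genome_set)",
                           call. = FALSE)
    return(x)
  }
  stop("cannot interpret input as a genome", call. = FALSE)
}
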