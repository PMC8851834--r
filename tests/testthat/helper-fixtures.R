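# deterministic random DNA for ad-hoc fixtures
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k random positions
substitute_bases <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), k)
  x[pos] <- vapply(x[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  paste(x, collapse = "")
}

linear_genome <- function(seq, id = "g") {
  genome_set(id, seq, topology = "linear")
}
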