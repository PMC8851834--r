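Package: orgamosaic
Title: Comparative Analysis of Plant Organelle Genome Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dissects plant mitochondrial genomes into homology classes
    (conserved, plastid-like, repetitive, genus- or species-specific, other),
    attributes specific sequences to candidate horizontal-transfer donors and
    computes cross-genome coverage matrices, builds fragment-anchor synteny
    maps, detects the plastome quadripartite architecture and its inverted
    repeat boundaries, and analyses mitochondrial gene fission events
    (breakpoints, intronic insertions, coding expansions, cis/trans splicing
    evidence) of the ccmFc type. Includes a native seed-and-extend nucleotide
    homology engine and a synthetic organelle genome simulator with planted
    truth tables so every analysis can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
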