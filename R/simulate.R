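#' @name synthetic_data
#' @title Synthetic organelle genomes with planted truth
#'
#' @description
#' Generators for families of related circular mitogenomes (with planted
#' plastid insertions, dispersed repeats, genus/species-specific segments and
#' partially shared blocks), quadripartite plastomes, gene-fission fixtures
#' reproducing the ccmFc layouts, and transcriptome-like coverage profiles.
#' Every planted feature is recorded in a truth table so downstream analyses
#' can be validated exactly, with no external data.
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# non-stop codons (and optionally non-ATG), for engineering open reading
# frames of known extent
rand_codons <- function(n, exclude = c("TAA", "TAG", "TGA")) {
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  pool <- setdiff(all_codons, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# point substitutions at `rate`, plus short indels at `indel_rate`
mutate_seq <- function(seq, rate, indel_rate = 0) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  hit <- which(stats::runif(n) < rate)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1), "")
  }
  if (indel_rate > 0) {
    ind <- which(stats::runif(n) < indel_rate)
    if (length(ind)) {
      out <- character(0)
      prev <- 1L
      for (p in sort(ind)) {
        out <- c(out, x[prev:p])
        if (stats::runif(1) < 0.5) {
          out <- c(out, sample(BASES, sample(1:4, 1), replace = TRUE))  # ins
        } else {
          out <- out[seq_len(max(0L, length(out) - sample(1:4, 1)))]    # del
        }
        prev <- p + 1L
      }
      if (prev <= n) out <- c(out, x[prev:n])
      x <- out
    }
  }
  paste(x, collapse = "")
}

# substitute an exact fraction of positions to reach a target percent identity
diverge_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  k <- round(n * (100 - identity) / 100)
  if (k == 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  pos <- sample(n, k)
  x[pos] <- vapply(x[pos], function(b) sample(setdiff(BASES, b), 1), "")
  paste(x, collapse = "")
}

# random bases forced to mismatch `ref_bases` position by position; placed at
# feature junctions so planted breakpoints carry no accidental micro-homology
junction_guard <- function(ref_bases) {
  x <- strsplit(toupper(ref_bases), "")[[1]]
  paste(vapply(x, function(b) sample(setdiff(BASES, b), 1), ""), collapse = "")
}

#' Simulation configuration for a genome family
#'
#' Defaults emulate, at desk scale, a family of related circular mitogenomes:
#' a shared core mutated independently per genome, plastome-derived
#' insertions, a dispersed repeat family, a genus-shared segment per genus,
#' donor-derived species-specific segments, and a block shared by most (but
#' not all) family members. Core length defaults to 50 kb so that full
#' analyses run in seconds.
#'
#' @param n_genera,species_per_genus family layout.
#' @param core_len shared core length (bp).
#' @param substitution_rate per-base substitution probability per genome.
#' @param indel_rate per-base short-indel probability per genome.
#' @param plastid_insert_spec tibble (`len`, `identity`): plastome copies
#'   planted in every mitogenome.
#' @param repeat_spec tibble (`len`, `copies`, `identity`, `orientation`):
#'   dispersed repeat families planted in every mitogenome.
#' @param genus_specific_len length of the genus-shared private segment.
#' @param specific_spec tibble (`donor_order`, `len`): donor-derived
#'   species-specific segments planted per species; alternatively a list of
#'   such tibbles, one per genome, for asymmetric scenarios (e.g. one species
#'   receiving massive foreign DNA).
#' @param other_block_len length of the block shared by all but
#'   `other_block_absent` genomes (those bases are neither conserved in all
#'   nor specific — the "other" class).
#' @param other_block_absent how many genomes (from the end) lack the block.
#' @param plastome_len family plastome length.
#' @param donor_len length of each donor genome.
#' @param min_feature_gap minimum spacing between planted features (bp).
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genera = 3L, species_per_genus = 2L,
                       core_len = 50000L,
                       substitution_rate = 0.02, indel_rate = 5e-4,
                       plastid_insert_spec = tibble::tibble(
                         len = c(3000L, 2000L), identity = c(99, 99)),
                       repeat_spec = tibble::tibble(
                         len = 800L, copies = 3L, identity = 100,
                         orientation = "direct"),
                       genus_specific_len = 3000L,
                       specific_spec = tibble::tibble(
                         donor_order = c("Fabales", "Solanales"),
                         len = c(2500L, 2000L)),
                       other_block_len = 2000L,
                       other_block_absent = 1L,
                       plastome_len = 20000L,
                       donor_len = 9000L,
                       min_feature_gap = 500L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genera >= 1, species_per_genus >= 1, core_len > 0,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a family of mitogenomes with planted truth
#'
#' Builds the family described by a [sim_config()]: every genome is an
#' independently mutated copy of a shared ancestral core with its planted
#' features inserted at non-overlapping random positions. The returned truth
#' table records each base's true class (under species-level conservation
#' scope), the donor order of every specific segment, and genome sizes.
#'
#' @param config a [sim_config()].
#' @return A list with `genomes` (one `genome_set` holding mitogenomes, the
#'   family plastome and the donor pool with `taxon_order` labels) and
#'   `truth` (list: `classes` tibble with `seq_id`, `start`, `end`, `class`,
#'   `detail`; `sizes`; `config`).
#' @export
simulate_family <- function(config = sim_config()) {
  with_seed(config$seed, {
    core <- rand_dna(config$core_len)
    plastome <- rand_dna(config$plastome_len)
    genera <- paste0("Genus", LETTERS[seq_len(config$n_genera)])
    n_g <- config$n_genera * config$species_per_genus
    genus_segments <- stats::setNames(
      lapply(genera, function(g) rand_dna(config$genus_specific_len)), genera)
    other_block <- rand_dna(config$other_block_len)

    # one donor genome per species-specific segment
    donors <- list(); donor_meta <- list()
    sp_ids <- character(); sp_genus <- character(); sp_species <- character()
    for (gi in seq_len(config$n_genera)) {
      for (sj in seq_len(config$species_per_genus)) {
        sp_ids <- c(sp_ids, paste0(genera[gi], "_sp", sj))
        sp_genus <- c(sp_genus, genera[gi])
        sp_species <- c(sp_species, paste0("sp", sj))
      }
    }
    spec_for <- function(k) {
      if (is.data.frame(config$specific_spec)) config$specific_spec
      else config$specific_spec[[k]]
    }
    donor_segments <- vector("list", n_g)
    for (k in seq_len(n_g)) {
      segs <- character(0)
      spec <- spec_for(k)
      for (r in seq_len(nrow(spec))) {
        dseq <- rand_dna(config$donor_len)
        off <- sample(config$donor_len - spec$len[r] - 1L, 1)
        did <- paste0("donor_", spec$donor_order[r], "_", k, "_", r)
        donors[[did]] <- dseq
        donor_meta[[did]] <- spec$donor_order[r]
        segs <- c(segs, substring(dseq, off + 1L, off + spec$len[r]))
      }
      donor_segments[[k]] <- segs
    }

    mito <- list(); truth_rows <- list()
    for (k in seq_len(n_g)) {
      core_k <- mutate_seq(core, config$substitution_rate, config$indel_rate)
      feats <- list()
      add_feat <- function(seq, class, detail) {
        feats[[length(feats) + 1L]] <<- list(seq = seq, class = class,
                                             detail = detail)
      }
      ps <- config$plastid_insert_spec
      for (r in seq_len(nrow(ps))) {
        off <- sample(config$plastome_len - ps$len[r] - 1L, 1)
        cp <- diverge_to_identity(substring(plastome, off + 1L, off + ps$len[r]),
                                  ps$identity[r])
        add_feat(cp, "PLASTID_LIKE", "plastome")
      }
      rs <- config$repeat_spec
      for (r in seq_len(nrow(rs))) {
        motif <- rand_dna(rs$len[r])
        for (cp in seq_len(rs$copies[r])) {
          s <- diverge_to_identity(motif, rs$identity[r])
          if (rs$orientation[r] == "inverted" && cp %% 2L == 0L) s <- revcomp(s)
          add_feat(s, "REPETITIVE", paste0("repeat_fam", r))
        }
      }
      if (config$genus_specific_len > 0) {
        add_feat(mutate_seq(genus_segments[[sp_genus[k]]],
                            config$substitution_rate),
                 "SPECIFIC", "genus_segment")
      }
      spec <- spec_for(k)
      for (r in seq_len(nrow(spec))) {
        add_feat(donor_segments[[k]][r], "SPECIFIC",
                 paste0("donor:", spec$donor_order[r]))
      }
      if (config$other_block_len > 0 && k <= n_g - config$other_block_absent) {
        add_feat(mutate_seq(other_block, config$substitution_rate),
                 "OTHER", "partial_block")
      }
      # non-overlapping insertion points in the mutated core
      nf <- length(feats)
      Lc <- nchar(core_k)
      if (nf == 0) {
        mito[[sp_ids[k]]] <- core_k
        truth_rows[[k]] <- tibble::tibble(
          seq_id = sp_ids[k], start = 0L, end = Lc,
          class = "CONSERVED", detail = "core")
        next
      }
      repeat {
        pos <- sort(sample(seq(config$min_feature_gap,
                               Lc - config$min_feature_gap), nf))
        if (nf < 2 || all(diff(pos) >= config$min_feature_gap)) break
      }
      pieces <- character(0); rows <- list(); cursor <- 0L; at <- 0L
      for (i in seq_len(nf)) {
        corepart <- substring(core_k, cursor + 1L, pos[i])
        if (nchar(corepart) > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            start = at, end = at + nchar(corepart), class = "CONSERVED",
            detail = "core")
          at <- at + nchar(corepart)
          pieces <- c(pieces, corepart)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          start = at, end = at + nchar(feats[[i]]$seq),
          class = feats[[i]]$class, detail = feats[[i]]$detail)
        at <- at + nchar(feats[[i]]$seq)
        pieces <- c(pieces, feats[[i]]$seq)
        cursor <- pos[i]
      }
      tailpart <- substring(core_k, cursor + 1L, Lc)
      if (nchar(tailpart) > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          start = at, end = at + nchar(tailpart), class = "CONSERVED",
          detail = "core")
        at <- at + nchar(tailpart)
        pieces <- c(pieces, tailpart)
      }
      mito[[sp_ids[k]]] <- paste(pieces, collapse = "")
      truth_rows[[k]] <- tibble::tibble(seq_id = sp_ids[k],
                                        dplyr::bind_rows(rows))
    }

    gs <- genome_set(
      id = c(sp_ids, "family_plastome", names(donors)),
      seq = c(unlist(mito, use.names = FALSE), plastome,
              unlist(donors, use.names = FALSE)),
      genus = c(sp_genus, NA, rep(NA, length(donors))),
      species = c(sp_species, NA, rep(NA, length(donors))),
      topology = c(rep("circular", n_g), "circular",
                   rep("linear", length(donors))),
      role = c(rep("mitogenome", n_g), "plastome",
               rep("donor", length(donors)))
    )
    gs$taxon_order <- c(rep(NA_character_, n_g + 1L),
                        unlist(donor_meta, use.names = FALSE))
    truth <- list(classes = dplyr::bind_rows(truth_rows),
                  sizes = stats::setNames(nchar(c(unlist(mito))), sp_ids),
                  config = config)
    list(genomes = gs, truth = truth)
  })
}

#' Apply inversions or translocations to a genome
#'
#' Rearranges a sequence by reverse-complementing (inversion) or excising and
#' re-inserting (translocation) non-overlapping random segments, recording
#' the affected intervals.
#'
#' @param seq DNA string.
#' @param n_inversions,n_translocations how many events of each kind.
#' @param min_len,max_len event length range (bp).
#' @param seed integer seed.
#' @return A list with `seq` (rearranged) and `events` (tibble: `type`,
#'   `start`, `end` on the input frame, and `dest` for translocations).
#' @export
apply_rearrangements <- function(seq, n_inversions = 1L, n_translocations = 0L,
                                 min_len = 2000L, max_len = 5000L, seed = 1L) {
  with_seed(seed, {
    L <- nchar(seq)
    k <- n_inversions + n_translocations
    gap_min <- 1000L
    len <- sample(min_len:max_len, k, replace = TRUE)
    free <- L - 2L * gap_min - sum(len) - (k - 1L) * gap_min
    if (free < 0) {
      stop("sequence too short for the requested rearrangements", call. = FALSE)
    }
    u <- sort(stats::runif(k)) * free
    start <- as.integer(gap_min + c(0L, cumsum(len[-k] + gap_min))[seq_len(k)] + u)
    events <- tibble::tibble(
      type = c(rep("inversion", n_inversions),
               rep("translocation", n_translocations)),
      start = start, end = start + len, dest = NA_integer_)
    out <- seq
    for (i in seq_len(n_inversions)) {
      a <- events$start[i]; b <- events$end[i]
      out <- paste0(substring(out, 1, a),
                    revcomp(substring(out, a + 1L, b)),
                    substring(out, b + 1L, nchar(out)))
    }
    if (n_translocations > 0) {
      for (i in (n_inversions + 1L):k) {
        a <- events$start[i]; b <- events$end[i]
        piece <- substring(out, a + 1L, b)
        rest <- paste0(substring(out, 1, a), substring(out, b + 1L, nchar(out)))
        dest <- sample(c(seq(500L, max(501L, a - 3000L)),
                         seq(min(nchar(rest) - 500L, a + 3000L),
                             nchar(rest) - 500L)), 1)
        events$dest[i] <- dest
        out <- paste0(substring(rest, 1, dest), piece,
                      substring(rest, dest + 1L, nchar(rest)))
      }
    }
    list(seq = out, events = events)
  })
}

#' Simulate a quadripartite plastome
#'
#' A circular plastome with the canonical LSC-IRb-SSC-IRa architecture
#' (IRa = reverse complement of IRb) at chosen region lengths; desk-scale
#' defaults keep full runs fast while preserving the LSC > SSC convention.
#'
#' @param lsc_len,ir_len,ssc_len region lengths (bp).
#' @param rotate rotate the final circle by this many bases (the map truth
#'   is invariant; useful for testing rotation invariance).
#' @param seed integer seed.
#' @return A list with `genome` (one-row `genome_set`) and `truth` (region
#'   intervals on the unrotated frame plus `rotation`).
#' @export
simulate_plastome <- function(lsc_len = 20000L, ir_len = 6000L,
                              ssc_len = 4000L, rotate = 0L, seed = 1L) {
  with_seed(seed, {
    lsc <- rand_dna(lsc_len)
    irb <- rand_dna(ir_len)
    ssc <- rand_dna(ssc_len)
    # guard the single-copy ends so the planted IR boundaries are exact:
    # an inverted extension across a junction pairs the first bases of a
    # single-copy region with the complement of its last bases
    guard_ends <- function(x) {
      n <- nchar(x)
      head2 <- junction_guard(revcomp(substring(x, n - 1L, n)))
      paste0(head2, substring(x, 3L, n))
    }
    lsc <- guard_ends(lsc)
    ssc <- guard_ends(ssc)
    full <- paste0(lsc, irb, ssc, revcomp(irb))
    L <- nchar(full)
    rotate <- rotate %% L
    if (rotate > 0) {
      full <- paste0(substring(full, rotate + 1L, L), substring(full, 1, rotate))
    }
    truth <- list(
      lsc = c(0L, lsc_len),
      irb = c(lsc_len, lsc_len + ir_len),
      ssc = c(lsc_len + ir_len, lsc_len + ir_len + ssc_len),
      ira = c(lsc_len + ir_len + ssc_len, L),
      ir_len = ir_len, rotation = rotate)
    list(genome = genome_set("sim_plastome", full, topology = "circular",
                             role = "plastome"),
         truth = truth)
  })
}

#' Simulate a gene-fission fixture
#'
#' Builds a reference genome carrying an intact two-exon gene (exon1 732 nt,
#' group II intron 1100 nt with a 48-nt binding window, exon2 600 nt) and a
#' target genome in which the gene has broken according to a named layout:
#'
#' * `intact` — unbroken copy of the whole gene region.
#' * `leafy` — first break deletes reference codons 164-206 (43 aa, 129 nt)
#'   near the 3' end of exon1; second break splits the intron cleanly; FR2
#'   and FR3 stay adjacent with a 3,500 bp insertion (containing a 2,800 bp
#'   plastome copy) in between.
#' * `sweet_potato` — the leafy layout; the engineered downstream stop
#'   (185 codons past the FR1 break) and upstream ATG (118 codons before
#'   the FR2 break) quantify the coding expansions.
#' * `epilinum` — insertion reduced to 1,300 bp (800 bp plastid-derived).
#' * `grammica` — FR2 and FR3 relocated to distant loci (connection broken).
#' * `americana` — leafy layout plus a 28 bp insertion inside the 48-nt
#'   intron binding window.
#' * `dodder_truncated` — leafy layout with a planted nonsense codon 10
#'   codons into the first gene's expansion.
#'
#' All layouts carry the engineered stop/ATG so expansion scans are
#' well-defined; feature junctions are guarded against accidental
#' micro-homology so the planted breakpoints are unambiguous. An optional
#' substitution rate mutates the target (not the reference).
#'
#' @param preset layout name.
#' @param seed integer seed.
#' @param sub_rate substitution rate applied to the target genome.
#' @return A list with `target`, `ref` (one-row `genome_set`s), `model`
#'   (`gene_models` row with binding window), `plastome`, and `truth` (all
#'   planted coordinates and quantities).
#' @export
simulate_fission_fixture <- function(preset = c("intact", "leafy",
                                                "sweet_potato", "epilinum",
                                                "grammica", "americana",
                                                "dodder_truncated"),
                                     seed = 1L, sub_rate = 0) {
  preset <- match.arg(preset)
  with_seed(seed, {
    exon1_len <- 732L; intron_len <- 1100L; exon2_len <- 600L
    break1_a <- 489L            # FR1 = codons 1..163 of exon1
    del_len <- 129L             # codons 164..206 lost at break 1
    break2_off <- 400L          # intron split point
    bind_off <- 700L; bind_len <- 48L
    exp1_aa <- 185L; exp2_aa <- 118L

    cds <- paste0("ATG", rand_codons((exon1_len + exon2_len) / 3 - 2), "TAA")
    exon1 <- substring(cds, 1, exon1_len)
    exon2 <- substring(cds, exon1_len + 1, exon1_len + exon2_len)
    intron <- rand_dna(intron_len)
    region <- paste0(exon1, intron, exon2)
    region_len <- nchar(region)

    flank <- function(n) rand_dna(n)
    ref_seq <- paste0(flank(1500), region, flank(1500))
    gene_start <- 1500L
    model <- gene_model(
      "ccmFc", "ref_genome",
      exon_starts = c(gene_start, gene_start + exon1_len + intron_len),
      exon_ends = c(gene_start + exon1_len,
                    gene_start + exon1_len + intron_len + exon2_len),
      strand = "+",
      binding_start = gene_start + exon1_len + bind_off,
      binding_end = gene_start + exon1_len + bind_off + bind_len)
    ref <- genome_set("ref_genome", ref_seq, genus = "Solanum",
                      topology = "linear")

    # region-coordinate fragments
    fr1 <- substring(region, 1, break1_a)
    fr2_start <- break1_a + del_len
    break2 <- exon1_len + break2_off
    fr2 <- substring(region, fr2_start + 1L, break2)
    fr3 <- substring(region, break2 + 1L, region_len)
    bind_region_start_in_fr3 <- exon1_len + bind_off - break2  # offset in fr3

    # engineered expansion flanks; the junction codons are constrained to
    # mismatch the reference continuation so the planted breakpoints carry
    # no accidental micro-homology
    stops <- c("TAA", "TAG", "TGA")
    stop_at <- if (preset == "dodder_truncated") 10L else exp1_aa
    repeat {
      first_codon <- rand_codons(1L)
      if (substring(first_codon, 1, 1) !=
            substring(region, break1_a + 1L, break1_a + 1L) &&
          substring(first_codon, 2, 2) !=
            substring(region, break1_a + 2L, break1_a + 2L)) break
    }
    ext1 <- paste0(first_codon, rand_codons(stop_at - 1L), "TAA", rand_dna(600))
    repeat {
      last_codon <- rand_codons(1L, exclude = c(stops, "ATG"))
      if (substring(last_codon, 2, 2) !=
            substring(region, fr2_start - 1L, fr2_start - 1L) &&
          substring(last_codon, 3, 3) !=
            substring(region, fr2_start, fr2_start)) break
    }
    up2 <- paste0(rand_dna(600),
                  "ATG", rand_codons(exp2_aa - 2L, exclude = c(stops, "ATG")),
                  last_codon)

    plastome_seq <- rand_dna(12000)
    plastome <- genome_set("fix_plastome", plastome_seq, topology = "circular",
                           role = "plastome")
    make_insert <- function(total, plastid) {
      pad <- (total - plastid) %/% 2L
      off <- 4000L
      paste0(junction_guard(substring(region, break2 + 1L, break2 + 2L)),
             rand_dna(pad - 4L),
             junction_guard(substring(plastome_seq, off - 1L, off)),
             substring(plastome_seq, off + 1L, off + plastid),
             junction_guard(substring(plastome_seq, off + plastid + 1L,
                                      off + plastid + 2L)),
             rand_dna(total - pad - plastid - 4L),
             junction_guard(substring(region, break2 - 1L, break2)))
    }
    ins_len <- switch(preset, epilinum = 1300L, 3500L)
    plastid_len <- switch(preset, epilinum = 800L, 2800L)

    fr3_target <- fr3
    bind_insert_len <- 0L
    if (preset == "americana") {
      bind_insert_len <- 28L
      at <- bind_region_start_in_fr3 + 24L
      wnext <- substring(fr3, at + 1L, at + 2L)
      ins28 <- paste0(junction_guard(wnext), rand_dna(24),
                      junction_guard(substring(fr3, at - 1L, at)))
      fr3_target <- paste0(substring(fr3, 1, at), ins28,
                           substring(fr3, at + 1L, nchar(fr3)))
    }

    if (preset == "intact") {
      tseq <- paste0(flank(1200), region, flank(1200))
      truth_frag <- tibble::tibble(label = "FR1", t_start = 1200L,
                                   t_end = 1200L + region_len)
      status <- "intact"; ins <- NA_integer_; pl <- NA_integer_
    } else if (preset == "grammica") {
      locusA <- paste0(flank(900), fr1, ext1)
      locusB <- paste0(flank(400), up2, fr2,
                       junction_guard(substring(region, break2 + 1L, break2 + 2L)),
                       rand_dna(11998))
      locusC <- paste0(rand_dna(7998),
                       junction_guard(substring(region, break2 - 1L, break2)),
                       fr3_target, flank(700))
      tseq <- paste0(locusA, locusB, locusC)
      a1 <- 900L
      b2 <- nchar(locusA) + 400L + nchar(up2)
      c3 <- nchar(locusA) + nchar(locusB) + 8000L
      truth_frag <- tibble::tibble(
        label = c("FR1", "FR2", "FR3"),
        t_start = c(a1, b2, c3),
        t_end = c(a1 + nchar(fr1), b2 + nchar(fr2), c3 + nchar(fr3_target)))
      status <- "separated"; ins <- NA_integer_; pl <- NA_integer_
    } else {
      insert <- make_insert(ins_len, plastid_len)
      locusA <- paste0(flank(900), fr1, ext1)
      locusB <- paste0(flank(400), up2, fr2, insert, fr3_target, flank(800))
      tseq <- paste0(locusA, locusB)
      a1 <- 900L
      b2 <- nchar(locusA) + 400L + nchar(up2)
      b3 <- b2 + nchar(fr2) + ins_len
      truth_frag <- tibble::tibble(
        label = c("FR1", "FR2", "FR3"),
        t_start = c(a1, b2, b3),
        t_end = c(a1 + nchar(fr1), b2 + nchar(fr2), b3 + nchar(fr3_target)))
      status <- "adjacent"; ins <- ins_len; pl <- plastid_len
    }
    if (sub_rate > 0) tseq <- mutate_seq(tseq, sub_rate)
    target <- genome_set(paste0("target_", preset), tseq, genus = "Cuscuta",
                         topology = "linear")
    truth <- list(
      preset = preset,
      fragments = truth_frag,
      break1_lost_aa = if (preset == "intact") 0L else del_len %/% 3L,
      break1_lost_nt = if (preset == "intact") 0L else del_len,
      break1_codons = c(break1_a %/% 3L + 1L, (break1_a + del_len) %/% 3L),
      break2_lost_nt = 0L,
      status = status, insertion_len = ins, plastid_bp = pl,
      expansion1_aa = stop_at, expansion2_aa = exp2_aa,
      truncated = preset == "dodder_truncated",
      full_expansion_aa = exp1_aa,
      binding_insert_len = bind_insert_len,
      binding_len = bind_len,
      region_len = region_len
    )
    list(target = target, ref = ref, model = model, plastome = plastome,
         truth = truth)
  })
}

#' Simulate a transcriptome-like coverage profile
#'
#' Poisson depth around `base_depth` over the expressed intervals, a
#' regime-dependent depth over the connecting (intron-side) interval —
#' mean 10 under `trans_like` (separately transcribed precursors), 0.8 x
#' `base_depth` under `cis_like` (one precursor spanning the connection) —
#' and background mean 2 elsewhere.
#'
#' @param genome_length profile length (bp).
#' @param expressed_intervals tibble (`start`, `end`), 0-based half-open.
#' @param connecting_interval length-2 vector `c(start, end)` of the
#'   intron-side/connecting region, or NULL.
#' @param regime "cis_like" or "trans_like".
#' @param base_depth expressed depth (reads).
#' @param seed integer seed.
#' @return Integer vector of per-base depths.
#' @export
simulate_coverage <- function(genome_length, expressed_intervals,
                              connecting_interval = NULL,
                              regime = c("cis_like", "trans_like"),
                              base_depth = 500, seed = 1L) {
  regime <- match.arg(regime)
  with_seed(seed, {
    depth <- stats::rpois(genome_length, 2)
    for (i in seq_len(nrow(expressed_intervals))) {
      a <- expressed_intervals$start[i]; b <- expressed_intervals$end[i]
      depth[(a + 1L):b] <- stats::rpois(b - a, base_depth)
    }
    if (!is.null(connecting_interval)) {
      a <- connecting_interval[1]; b <- connecting_interval[2]
      mu <- if (regime == "trans_like") 10 else 0.8 * base_depth
      depth[(a + 1L):b] <- stats::rpois(b - a, mu)
    }
    as.integer(depth)
  })
}

#' Coverage profile for a fission fixture
#'
#' Convenience wrapper: expresses the planted fragment loci of a
#' [simulate_fission_fixture()] and fills the FR2-FR3 connecting region
#' according to the chosen splicing regime.
#'
#' @param fixture a fission fixture list.
#' @param regime "cis_like" or "trans_like".
#' @param base_depth expressed depth.
#' @param seed integer seed.
#' @return Integer vector of per-base depths over the fixture target.
#' @export
fixture_coverage <- function(fixture, regime = c("cis_like", "trans_like"),
                             base_depth = 500, seed = 1L) {
  regime <- match.arg(regime)
  tf <- fixture$truth$fragments
  conn <- NULL
  if (identical(fixture$truth$status, "adjacent") && nrow(tf) >= 3) {
    conn <- c(tf$t_end[tf$label == "FR2"], tf$t_start[tf$label == "FR3"])
  }
  simulate_coverage(fixture$target$length[1],
                    tibble::tibble(start = tf$t_start, end = tf$t_end),
                    connecting_interval = conn, regime = regime,
                    base_depth = base_depth, seed = seed)
}
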