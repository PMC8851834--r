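test_that("an intact gene copy yields a single full-span fragment", {
  fx <- simulate_fission_fixture("intact", seed = 111)
  fr <- locate_fragments(fx$target, fx$ref, fx$model)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$q_start, 0L)
  expect_equal(fr$q_end, fx$truth$region_len)
})

test_that("the leafy layout yields three fragments at their planted loci", {
  fx <- simulate_fission_fixture("leafy", seed = 112)
  fr <- locate_fragments(fx$target, fx$ref, fx$model)
  expect_equal(fr$label, c("FR1", "FR2", "FR3"))
  expect_equal(fr$t_start, fx$truth$fragments$t_start)
  expect_equal(fr$t_end, fx$truth$fragments$t_end)
  expect_true(all(fr$identity == 100))
})

test_that("breakpoint losses match the planted deletion", {
  fx <- simulate_fission_fixture("leafy", seed = 113)
  fr <- locate_fragments(fx$target, fx$ref, fx$model)
  bp <- infer_breakpoints(fr, fx$ref, fx$model)
  expect_equal(bp$break1_lost_aa, 43L)
  expect_equal(bp$break1_lost_nt, 129L)
  expect_equal(bp$break1_codons, c(164L, 206L))   # tomato coordinates
  expect_equal(bp$break2_lost_nt, 0L)             # clean intron split
  expect_error(infer_breakpoints(fr[1, ], fx$ref, fx$model), "two fragments")
})

test_that("abutting fragments report a zero-length break", {
  set.seed(114)
  fx <- simulate_fission_fixture("intact", seed = 114)
  region_len <- fx$truth$region_len
  # fabricate two fragments that abut on the reference
  fr <- tibble::tibble(
    label = c("FR1", "FR2"), q_start = c(0L, 489L), q_end = c(489L, region_len),
    t_seq = "t", t_start = c(100L, 4000L), t_end = c(589L, 4000L + region_len - 489L),
    strand = "+", identity = 100, aln_len = c(489L, region_len - 489L),
    gap_opens = 0L)
  bp <- infer_breakpoints(fr, fx$ref, fx$model)
  expect_equal(bp$break1_lost_aa, 0L)
  # overlap beyond the word size is inconsistent
  fr_bad <- fr
  fr_bad$q_start[2] <- 400L
  expect_error(infer_breakpoints(fr_bad, fx$ref, fx$model), "overlap")
})

test_that("the gap analyzer measures the planted insertion and its plastid content", {
  fx <- simulate_fission_fixture("leafy", seed = 115)
  fr <- locate_fragments(fx$target, fx$ref, fx$model)
  g <- analyze_gap(fx$target, fr, fx$plastome)
  expect_equal(g$status, "adjacent")
  expect_equal(g$insertion_len, 3500L)
  expect_equal(g$plastid_bp, 2800L)

  fe <- simulate_fission_fixture("epilinum", seed = 116)
  fre <- locate_fragments(fe$target, fe$ref, fe$model)
  ge <- analyze_gap(fe$target, fre, fe$plastome)
  expect_equal(ge$insertion_len, 1300L)

  fg <- simulate_fission_fixture("grammica", seed = 117)
  frg <- locate_fragments(fg$target, fg$ref, fg$model)
  gg <- analyze_gap(fg$target, frg, fg$plastome)
  expect_equal(gg$status, "separated")
  expect_true(is.na(gg$insertion_len))
})

test_that("expansion scans find the planted stop and start codons", {
  fx <- simulate_fission_fixture("sweet_potato", seed = 118)
  fr <- locate_fragments(fx$target, fx$ref, fx$model)
  ex <- scan_expansion(fx$target, fr, fx$ref, fx$model)
  expect_equal(ex$ccmFc1_aa, 185L)
  expect_equal(ex$ccmFc2_aa, 118L)
  expect_true(is.na(ex$truncated_at))

  # a stop placed immediately after the break gives a zero expansion
  ft <- simulate_fission_fixture("leafy", seed = 119)
  frt <- locate_fragments(ft$target, ft$ref, ft$model)
  seqs <- strsplit(ft$target$seq, "")[[1]]
  p <- frt$t_end[frt$label == "FR1"]
  seqs[(p + 1):(p + 3)] <- c("T", "A", "A")
  t2 <- genome_set(ft$target$id, paste(seqs, collapse = ""),
                   topology = "linear")
  ex0 <- scan_expansion(t2, frt, ft$ref, ft$model)
  expect_equal(ex0$ccmFc1_aa, 0L)

  # planted nonsense mutation truncates the first gene's expansion
  fd <- simulate_fission_fixture("dodder_truncated", seed = 120)
  frd <- locate_fragments(fd$target, fd$ref, fd$model)
  exd <- scan_expansion(fd$target, frd, fd$ref, fd$model,
                        full_expansion_aa = 185L)
  expect_equal(exd$ccmFc1_aa, 10L)
  expect_equal(exd$truncated_at, 10L)
})

test_that("gene copies classify as intact, pseudo or missing by the reading-frame rules", {
  fx <- simulate_fission_fixture("intact", seed = 121)
  lay_ex <- fx$model$exons[[1]]
  cds <- paste0(substring(fx$ref$seq, lay_ex$start[1] + 1, lay_ex$end[1]),
                substring(fx$ref$seq, lay_ex$start[2] + 1, lay_ex$end[2]))
  ref_protein <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))

  expect_equal(classify_gene_status(cds, ref_protein), "intact")

  mid <- 600L  # internal TAA at a codon boundary
  pseudo_stop <- paste0(substring(cds, 1, mid), "TAA",
                        substring(cds, mid + 4, nchar(cds)))
  expect_equal(classify_gene_status(pseudo_stop, ref_protein), "pseudo")

  frameshift <- paste0(substring(cds, 1, 700), substring(cds, 702, nchar(cds)))
  expect_equal(classify_gene_status(frameshift, ref_protein), "pseudo")

  truncated <- substring(cds, 1, floor(nchar(cds) * 0.6) %/% 3 * 3)
  expect_equal(classify_gene_status(truncated, ref_protein), "pseudo")

  expect_equal(classify_gene_status(rdna(900, seed = 122), ref_protein),
               "missing")
  expect_equal(classify_gene_status("", ref_protein), "missing")
})

test_that("splicing calls follow the coverage rules at the 50/400 thresholds", {
  fx <- simulate_fission_fixture("leafy", seed = 123)
  fr <- locate_fragments(fx$target, fx$ref, fx$model)
  cov_t <- fixture_coverage(fx, "trans_like", base_depth = 500, seed = 124)
  expect_equal(splicing_call(cov_t, fr, fx$ref, fx$model), "trans")
  cov_c <- fixture_coverage(fx, "cis_like", base_depth = 500, seed = 125)
  expect_equal(splicing_call(cov_c, fr, fx$ref, fx$model), "cis")
  cov_lo <- fixture_coverage(fx, "trans_like", base_depth = 5, seed = 126)
  expect_equal(splicing_call(cov_lo, fr, fx$ref, fx$model), "ambiguous")
  cov0 <- rep(0L, fx$target$length)
  expect_warning(out <- splicing_call(cov0, fr, fx$ref, fx$model),
                 "ambiguous")
  expect_equal(out, "ambiguous")
})

test_that("binding region status distinguishes preserved, inserted and absent windows", {
  fx <- simulate_fission_fixture("leafy", seed = 127)
  br <- binding_region_check(fx$target, fx$ref, fx$model)
  expect_equal(br$status, "preserved")
  expect_equal(br$matched_len, 48L)

  fa <- simulate_fission_fixture("americana", seed = 128)
  bra <- binding_region_check(fa$target, fa$ref, fa$model)
  expect_equal(bra$status, "disrupted")
  expect_equal(bra$insertion_len, 28L)

  absent <- genome_set("absent", rdna(5000, seed = 129), topology = "linear")
  brx <- binding_region_check(absent, fx$ref, fx$model)
  expect_equal(brx$status, "disrupted")
  expect_true(is.na(brx$insertion_len))
})

test_that("fragment spans plus breakpoint losses conserve the reference length", {
  for (preset in c("leafy", "sweet_potato", "epilinum", "grammica")) {
    fx <- simulate_fission_fixture(preset, seed = 130)
    fr <- locate_fragments(fx$target, fx$ref, fx$model)
    bp <- infer_breakpoints(fr, fx$ref, fx$model)
    total <- sum(fr$q_end - fr$q_start) + bp$break1_lost_nt + bp$break2_lost_nt
    expect_equal(total, fx$truth$region_len,
                 label = paste("conservation for", preset))
  }
})

test_that("breakpoints are recovered within tolerance under 2% substitution noise", {
  exact <- 0L
  for (seed in 131:140) {
    fx <- simulate_fission_fixture("leafy", seed = seed, sub_rate = 0.02)
    fr <- locate_fragments(fx$target, fx$ref, fx$model)
    expect_equal(nrow(fr), 3L)
    bp <- infer_breakpoints(fr, fx$ref, fx$model)
    expect_lte(abs(bp$break1_lost_nt - 129L), 3L)
    expect_lte(abs(bp$break2_lost_nt - 0L), 3L)
    if (bp$break1_lost_nt == 129L) exact <- exact + 1L
  }
  # clean fixtures recover exactly
  fx0 <- simulate_fission_fixture("leafy", seed = 141, sub_rate = 0)
  fr0 <- locate_fragments(fx0$target, fx0$ref, fx0$model)
  expect_equal(infer_breakpoints(fr0, fx0$ref, fx0$model)$break1_lost_nt, 129L)
})

test_that("the orchestrated report collects all components", {
  fx <- simulate_fission_fixture("leafy", seed = 142)
  cov <- fixture_coverage(fx, "trans_like", seed = 143)
  rep <- analyze_fission(fx$target, fx$ref, fx$model,
                         plastomes = fx$plastome, coverage = cov)
  expect_s3_class(rep, "fission_report")
  g <- glance(rep)
  expect_equal(g$n_fragments, 3L)
  expect_equal(g$break1_lost_aa, 43L)
  expect_equal(g$insertion_len, 3500L)
  expect_equal(g$plastid_bp, 2800L)
  expect_equal(g$expansion1_aa, 185L)
  expect_equal(g$expansion2_aa, 118L)
  expect_equal(g$binding_status, "preserved")
  expect_equal(g$splicing, "trans")
  expect_equal(nrow(tidy(rep)), 3L)
  expect_output(print(rep), "43 aa")
})
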