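test_that("the generator is byte-deterministic under a fixed seed", {
  f1 <- simulate_family(sim_config(seed = 151, core_len = 8000L))
  f2 <- simulate_family(sim_config(seed = 151, core_len = 8000L))
  expect_identical(f1$genomes$seq, f2$genomes$seq)
  expect_identical(f1$truth$classes, f2$truth$classes)
  f3 <- simulate_family(sim_config(seed = 152, core_len = 8000L))
  expect_false(identical(f1$genomes$seq, f3$genomes$seq))

  x1 <- simulate_fission_fixture("leafy", seed = 153)
  x2 <- simulate_fission_fixture("leafy", seed = 153)
  expect_identical(x1$target$seq, x2$target$seq)
  expect_identical(x1$plastome$seq, x2$plastome$seq)
})

test_that("zero rates and zero features reproduce the shared core exactly", {
  cfg <- sim_config(
    seed = 154, core_len = 5000L,
    substitution_rate = 0, indel_rate = 0,
    plastid_insert_spec = tibble::tibble(len = integer(), identity = numeric()),
    repeat_spec = tibble::tibble(len = integer(), copies = integer(),
                                 identity = numeric(), orientation = character()),
    genus_specific_len = 0L,
    specific_spec = tibble::tibble(donor_order = character(), len = integer()),
    other_block_len = 0L)
  fam <- simulate_family(cfg)
  mitos <- fam$genomes[fam$genomes$role == "mitogenome", ]
  expect_equal(length(unique(mitos$seq)), 1L)
  expect_equal(unique(mitos$length), 5000L)
  expect_true(all(fam$truth$classes$class == "CONSERVED"))
})

test_that("planted truth intervals are disjoint and within genome bounds", {
  fam <- simulate_family(sim_config(seed = 155))
  tr <- fam$truth$classes
  gs <- fam$genomes
  for (id in unique(tr$seq_id)) {
    t1 <- tr[tr$seq_id == id, ]
    t1 <- t1[order(t1$start), ]
    expect_true(all(t1$end > t1$start))
    expect_true(all(t1$start[-1] >= t1$end[-nrow(t1)]))
    expect_equal(max(t1$end), gs$length[gs$id == id])
    expect_equal(min(t1$start), 0L)
  }
})

test_that("an asymmetric specific load inflates one genome as planted", {
  # one species receives ~60% foreign content and roughly doubles in size
  big <- tibble::tibble(donor_order = rep(c("Fabales", "Rosales", "Apiales"), 4),
                        len = rep(3000L, 12))
  none <- tibble::tibble(donor_order = character(), len = integer())
  cfg <- sim_config(seed = 156, core_len = 20000L,
                    genus_specific_len = 0L, other_block_len = 0L,
                    plastid_insert_spec = tibble::tibble(len = 1500L,
                                                         identity = 99),
                    specific_spec = list(big, none, none, none, none, none))
  fam <- simulate_family(cfg)
  sizes <- fam$truth$sizes
  expect_gt(sizes[1] / mean(sizes[-1]), 1.8)
  tr <- fam$truth$classes
  sp1 <- tr[tr$seq_id == names(sizes)[1] & tr$class == "SPECIFIC", ]
  expect_gt(sum(sp1$end - sp1$start) / sizes[1], 0.55)
})

test_that("fixture truth tables are internally consistent", {
  fx <- simulate_fission_fixture("leafy", seed = 157)
  tt <- fx$truth
  expect_equal(tt$insertion_len, 3500L)
  expect_equal(tt$plastid_bp, 2800L)
  # the planted insertion is the distance between the planted FR2/FR3 loci
  tf <- tt$fragments
  expect_equal(tf$t_start[tf$label == "FR3"] - tf$t_end[tf$label == "FR2"],
               tt$insertion_len)
  expect_equal(tt$break1_lost_nt, 3L * tt$break1_lost_aa)
  expect_equal(tt$break1_codons, c(164L, 206L))
  # fragment intervals fit in the target
  expect_true(all(tf$t_end <= fx$target$length))
})

test_that("simulated coverage honours regimes and intervals", {
  cov <- simulate_coverage(2000L,
                           tibble::tibble(start = 500L, end = 1000L),
                           connecting_interval = c(1200L, 1500L),
                           regime = "trans_like", base_depth = 500,
                           seed = 158)
  expect_equal(length(cov), 2000L)
  expect_gt(median(cov[501:1000]), 400)
  expect_lt(median(cov[1201:1500]), 50)
  expect_lt(median(cov[1:500]), 10)
  cov2 <- simulate_coverage(2000L,
                            tibble::tibble(start = 500L, end = 1000L),
                            connecting_interval = c(1200L, 1500L),
                            regime = "cis_like", base_depth = 500,
                            seed = 159)
  expect_gt(median(cov2[1201:1500]), 0.5 * median(cov2[501:1000]))
})

test_that("rearrangement events are recorded and reproducible", {
  a <- rdna(20000, seed = 160)
  r1 <- apply_rearrangements(a, n_inversions = 2, min_len = 2000,
                             max_len = 4000, seed = 161)
  r2 <- apply_rearrangements(a, n_inversions = 2, min_len = 2000,
                             max_len = 4000, seed = 161)
  expect_identical(r1$seq, r2$seq)
  expect_equal(nrow(r1$events), 2L)
  expect_equal(nchar(r1$seq), nchar(a))
  # the inverted interval matches its reverse complement in the source
  e <- r1$events[1, ]
  expect_equal(substring(r1$seq, e$start + 1, e$end),
               revcomp(substring(a, e$start + 1, e$end)))
})
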