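# small hand-built family: focal plus others, linear for speed
build_toy_family <- function() {
  set.seed(31)
  core <- rdna(8000)
  pt <- rdna(6000)
  plastid_insert <- substr(pt, 2001, 3000)
  donorseg <- rdna(1200)
  focal_seq <- paste0(substr(core, 1, 3000), plastid_insert,
                      substr(core, 3001, 6000), donorseg,
                      substr(core, 6001, 8000))
  others <- genome_set(
    id = c("B1", "B2", "C1"),
    seq = c(substitute_bases(core, 150), substitute_bases(core, 150),
            substitute_bases(core, 150)),
    genus = c("GenB", "GenB", "GenC"), topology = "linear")
  list(focal = genome_set("A1", focal_seq, genus = "GenA", topology = "linear"),
       others = others,
       plastome = genome_set("pt", pt, topology = "circular", role = "plastome"),
       plastid_span = c(3000L, 4000L), donor_span = c(7000L, 8200L))
}

test_that("plastid-like intervals follow the >90% identity rule", {
  fam <- build_toy_family()
  pl <- plastid_like_intervals(fam$focal, fam$plastome)
  expect_equal(nrow(pl), 1L)
  expect_equal(c(pl$start, pl$end), fam$plastid_span)

  no_pt_focal <- linear_genome(rdna(3000, seed = 32))
  expect_equal(nrow(plastid_like_intervals(no_pt_focal, fam$plastome)), 0L)

  # a copy diverged to ~85% identity is below the rule
  diverged <- substitute_bases(substr(fam$plastome$seq, 2001, 3000), 150,
                               seed = 33)
  g <- linear_genome(paste0(rdna(2000, seed = 34), diverged,
                            rdna(2000, seed = 35)))
  expect_equal(nrow(plastid_like_intervals(g, fam$plastome)), 0L)
  expect_error(plastid_like_intervals(fam$focal, fam$plastome[0, ]),
               "plastome")
})

test_that("repetitive intervals follow the >95% self-identity rule", {
  x <- rdna(1000, seed = 36)
  g <- linear_genome(paste0(rdna(1500, seed = 37), x, rdna(1500, seed = 38), x))
  rp <- repetitive_intervals(g)
  expect_equal(nrow(rp), 2L)
  expect_equal(rp$end - rp$start, c(1000L, 1000L))

  # pair diverged to ~93% does not qualify
  g93 <- linear_genome(paste0(rdna(1500, seed = 39), x,
                              rdna(1500, seed = 40),
                              substitute_bases(x, 70, seed = 41)))
  expect_equal(nrow(repetitive_intervals(g93)), 0L)

  # a three-copy family collapses into one union of three intervals
  g3 <- linear_genome(paste0(x, rdna(1200, seed = 42), x,
                             rdna(1200, seed = 43), x))
  rp3 <- repetitive_intervals(g3)
  expect_equal(nrow(rp3), 3L)
  # a few bp of slack: chance matches at copy junctions legitimately extend
  expect_lte(abs(sum(rp3$end - rp3$start) - 3000L), 12L)
})

test_that("conserved intervals require homologs in all other family members", {
  fam <- build_toy_family()
  cv <- conserved_intervals(fam$focal, fam$others)
  # the core is conserved; the plastid insert and donor segment are not
  covered <- sum(cv$end - cv$start)
  expect_gt(covered, 7500)
  expect_lt(covered, 8100)
  in_cv <- function(p) any(cv$start <= p & p < cv$end)
  expect_false(in_cv(3500))   # inside plastid insert
  expect_false(in_cv(7600))   # inside donor segment

  # a block present in all but one member is excluded
  blk <- rdna(900, seed = 44)
  focal2 <- linear_genome(paste0(rdna(2000, seed = 45), blk, rdna(1000, seed = 46)))
  others2 <- genome_set(
    id = c("o1", "o2", "o3"),
    seq = c(paste0(rdna(800, seed = 47), blk), paste0(blk, rdna(700, seed = 48)),
            rdna(2500, seed = 49)),
    genus = "X", topology = "linear")
  cv2 <- conserved_intervals(focal2, others2)
  expect_false(any(cv2$start <= 2400 & 2400 < cv2$end))

  expect_error(conserved_intervals(fam$focal, rbind(fam$others, fam$focal)),
               "focal")
})

test_that("specific intervals are the complement of other-genus homology", {
  fam <- build_toy_family()
  sp <- specific_intervals(fam$focal, fam$others)
  # the donor segment and the plastid insert have no homologs in the family
  # (boundaries may shift a few bp through chance junction matches)
  expect_true(any(sp$start <= 7010 & sp$end >= 8190))
  expect_equal(unique(sp$scope), "genus")

  # focal identical to a congener: genus-specific yes, species-specific no
  seg <- rdna(1500, seed = 50)
  core <- rdna(4000, seed = 51)
  focal3 <- genome_set("f", paste0(core, seg), genus = "GenA",
                       topology = "linear")
  family3 <- genome_set(c("sib", "other"),
                        c(paste0(substitute_bases(core, 80, seed = 52), seg),
                          substitute_bases(core, 80, seed = 53)),
                        genus = c("GenA", "GenB"), topology = "linear")
  sp3 <- specific_intervals(focal3, family3)
  g_bp <- sum(sp3$end[sp3$scope == "genus"] - sp3$start[sp3$scope == "genus"])
  s_bp <- sum(sp3$end[sp3$scope == "species"] - sp3$start[sp3$scope == "species"])
  expect_gt(g_bp, 1400)
  expect_lt(s_bp, 50)

  # whole genome shared with another genus: nothing specific
  sp4 <- specific_intervals(
    genome_set("f2", core, genus = "GenA", topology = "linear"),
    genome_set(c("x1", "x2"), c(substitute_bases(core, 80, seed = 54), rdna(2000, seed = 55)),
               genus = c("GenB", "GenC"), topology = "linear"))
  expect_lt(sum(sp4$end - sp4$start), 60)
})

test_that("classification applies the fixed precedence and always tiles the genome", {
  fam <- build_toy_family()
  pr <- classify_genome(fam$focal, fam$others, fam$plastome)
  seg <- tidy(pr)
  expect_equal(seg$start[1], 0L)
  expect_equal(seg$end[nrow(seg)], pr$length)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))  # no gaps, no overlaps
  expect_equal(sum(pr$totals), pr$length)
  expect_equal(sum(pr$proportions), 1, tolerance = 1e-9)

  # a base inside both a repeat and a plastid insertion is PLASTID_LIKE
  pt <- fam$plastome$seq[1]
  dup <- substr(pt, 1001, 1800)  # two copies of a plastome stretch
  g <- genome_set("dup", paste0(rdna(2000, seed = 56), dup,
                                rdna(2000, seed = 57), dup,
                                rdna(1000, seed = 58)),
                  genus = "GenA", topology = "linear")
  pr2 <- classify_genome(g, fam$others, fam$plastome)
  seg2 <- tidy(pr2)
  cls_at <- function(p) seg2$class[seg2$start <= p & p < seg2$end]
  expect_equal(cls_at(2400), "PLASTID_LIKE")
  expect_equal(unname(pr2$totals["REPETITIVE"]), 0)
})

test_that("a genome with no homology anywhere is entirely specific", {
  fam <- build_toy_family()
  lone <- genome_set("lone", rdna(4000, seed = 59), genus = "GenZ",
                     topology = "linear")
  pr <- classify_genome(lone, fam$others, fam$plastome)
  expect_equal(unname(pr$proportions["SPECIFIC"]), 1)
})

test_that("raising the plastid identity floor never increases plastid-like bp", {
  fam <- build_toy_family()
  bp <- vapply(c(90, 95, 99.5), function(idmin) {
    pl <- plastid_like_intervals(fam$focal, fam$plastome,
                                 thresholds(plastid_identity_min = idmin))
    sum(pl$end - pl$start)
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("adding a family member never increases conserved or specific bp", {
  fam <- build_toy_family()
  extra <- genome_set("D1", rdna(5000, seed = 60), genus = "GenD",
                      topology = "linear")
  cv_small <- conserved_intervals(fam$focal, fam$others)
  cv_big <- conserved_intervals(fam$focal, rbind(fam$others, extra))
  expect_lte(sum(cv_big$end - cv_big$start), sum(cv_small$end - cv_small$start))
  sp_small <- specific_intervals(fam$focal, fam$others)
  sp_big <- specific_intervals(fam$focal, rbind(fam$others, extra))
  expect_lte(sum(sp_big$end - sp_big$start), sum(sp_small$end - sp_small$start))
})

test_that("class proportions are recovered from generator families", {
  # a few seeds here; the full 20-seed recovery study runs in the
  # acceptance suite
  for (seed in c(42, 43)) {
    fam <- simulate_family(sim_config(seed = seed))
    gs <- fam$genomes
    mitos <- gs[gs$role == "mitogenome", ]
    pr <- classify_genome(mitos[1, ], mitos[-1, ],
                          gs[gs$role == "plastome", ])
    tr <- fam$truth$classes
    tr <- tr[tr$seq_id == mitos$id[1], ]
    planted <- tapply(tr$end - tr$start, tr$class, sum)
    for (cl in names(planted)) {
      expect_lt(abs(pr$totals[[cl]] - planted[[cl]]) / pr$length, 0.02,
                label = paste(cl, "recovery for seed", seed))
    }
    seg <- tidy(pr)
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
    expect_equal(sum(pr$totals), pr$length)
  }
})
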