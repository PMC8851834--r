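make_attrib_fixture <- function() {
  set.seed(71)
  donor_fab <- rdna(6000)
  donor_ros <- rdna(6000)
  seg1 <- substr(donor_fab, 1001, 3000)   # 2 kb verbatim Fabales segment
  seg2 <- substr(donor_fab, 3501, 4300)   # 0.8 kb Fabales segment
  seg3 <- rdna(900)                       # unknown origin
  focal_seq <- paste0(rdna(500), seg1, rdna(400), seg2, rdna(400), seg3,
                      rdna(300))
  segments <- tibble::tibble(
    seq_id = "focal",
    start = c(500L, 2900L, 4100L),
    end = c(2500L, 3700L, 5000L))
  list(focal = genome_set("focal", focal_seq, genus = "Cuscuta",
                          topology = "linear"),
       donors = donor_db(c("d_fab", "d_ros"), c(donor_fab, donor_ros),
                         taxon_order = c("Fabales", "Rosales")),
       segments = segments)
}

test_that("segments attribute to the donor order of their best hit", {
  fx <- make_attrib_fixture()
  at <- attribute_segments(fx$segments, fx$focal, fx$donors)
  expect_equal(at$order, c("Fabales", "Fabales", "unknown"))
  expect_true(is.na(at$best_aln_len[3]))
  expect_error(attribute_segments(fx$segments, fx$focal, fx$donors[0, ]),
               "empty")
})

test_that("best hits shorter than the 100 bp rule give unknown", {
  set.seed(72)
  donor <- rdna(4000)
  short <- substr(donor, 501, 580)  # 80 bp of donor homology only
  focal <- genome_set("f", paste0(rdna(300), short, rdna(300)),
                      topology = "linear")
  segs <- tibble::tibble(seq_id = "f", start = 200L, end = 800L)
  at <- attribute_segments(segs, focal,
                           donor_db("d", donor, taxon_order = "Fabales"))
  expect_equal(at$order, "unknown")
})

test_that("order aggregation sums lengths and applies the 5 kb display rule", {
  at <- tibble::tibble(
    segment_id = paste0("s", 1:4), seq_id = "f",
    start = 0L, end = 0L,
    length = c(3000L, 3000L, 4000L, 700L),
    order = c("Fabales", "Fabales", "Rosales", "unknown"),
    donor_id = NA, best_bitscore = NA, best_aln_len = NA, best_identity = NA)
  ag <- aggregate_by_order(at)
  expect_equal(ag$total_bp[ag$order == "Fabales"], 6000L)
  expect_true(ag$display[ag$order == "Fabales"])
  expect_equal(ag$total_bp[ag$order == "Rosales"], 4000L)
  expect_false(ag$display[ag$order == "Rosales"])
  expect_true("unknown" %in% ag$order)
  expect_true(ag$display[ag$order == "unknown"])
  expect_equal(nrow(aggregate_by_order(at[0, ])), 0L)
  # every segment lands in exactly one attribution bucket
  expect_equal(sum(ag$total_bp), sum(at$length))
})

test_that("the HGT-like call is strictly greater than 500 bp", {
  at <- tibble::tibble(
    segment_id = paste0("s", 1:3), seq_id = "f", start = 0L, end = 0L,
    length = 1000L, order = "Fabales", donor_id = "d",
    best_bitscore = 1, best_aln_len = c(600L, 500L, NA), best_identity = 99)
  hg <- hgt_like(at)
  expect_equal(hg$segment_id, "s1")
})

test_that("coverage matrix entries are per-base union fractions in [0, 1]", {
  set.seed(73)
  seg <- rdna(1000)
  focal <- genome_set("f", paste0(rdna(200), seg, rdna(200)),
                      topology = "linear")
  segs <- tibble::tibble(seq_id = "f", start = 200L, end = 1200L)
  targets <- genome_set(
    id = c("full", "absent", "half"),
    seq = c(paste0(rdna(300), seg, rdna(300)),
            rdna(2000),
            paste0(rdna(300), substr(seg, 1, 500), rdna(500))),
    topology = "linear")
  cm <- coverage_matrix(segs, focal, targets)
  expect_equal(unname(cm[1, "full"]), 1.0)
  expect_equal(unname(cm[1, "absent"]), 0.0)
  expect_equal(unname(cm[1, "half"]), 0.5, tolerance = 0.02)
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("coverage is monotone in the planted content of the target", {
  set.seed(74)
  seg <- rdna(1200)
  focal <- genome_set("f", paste0(rdna(100), seg, rdna(100)),
                      topology = "linear")
  segs <- tibble::tibble(seq_id = "f", start = 100L, end = 1300L)
  fractions <- c(0.25, 0.5, 1)
  covs <- vapply(fractions, function(fr) {
    tg <- genome_set("t", paste0(rdna(400), substr(seg, 1, 1200 * fr),
                                 rdna(400)), topology = "linear")
    coverage_matrix(segs, focal, tg)[1, 1]
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("segments unique to one species stay uncovered in its relatives", {
  # one species acquires many foreign segments its relatives lack (the
  # inflated-mitogenome scenario); relatives' coverage stays near zero
  cfg <- sim_config(
    seed = 75,
    core_len = 20000L,
    specific_spec = list(
      tibble::tibble(donor_order = c("Fabales", "Rosales", "Sapindales"),
                     len = c(3000L, 2500L, 2000L)),
      tibble::tibble(donor_order = "Solanales", len = 800L),
      tibble::tibble(donor_order = "Solanales", len = 800L),
      tibble::tibble(donor_order = "Solanales", len = 800L),
      tibble::tibble(donor_order = "Solanales", len = 800L),
      tibble::tibble(donor_order = "Solanales", len = 800L)))
  fam <- simulate_family(cfg)
  gs <- fam$genomes
  mitos <- gs[gs$role == "mitogenome", ]
  donors <- gs[gs$role == "donor", ]
  focal <- mitos[1, ]
  tr <- fam$truth$classes
  planted <- tr[tr$seq_id == focal$id & grepl("^donor:", tr$detail), ]
  segs <- tibble::tibble(seq_id = focal$id,
                         start = planted$start, end = planted$end)
  at <- attribute_segments(segs, focal, donors)
  expect_true(all(at$order %in% c("Fabales", "Rosales", "Sapindales")))
  hg <- hgt_like(at)
  expect_gt(nrow(hg), 0)
  cm <- coverage_matrix(hg, focal, mitos[-1, ])
  expect_lt(mean(cm), 0.05)
})
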