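test_that("deletion simulation is reproducible and respects its bounds", {
  cfg <- sim_config(n_patients = 300)
  d1 <- simulate_deletions(cfg, seed = 5)
  d2 <- simulate_deletions(cfg, seed = 5)
  expect_identical(d1, d2)
  d3 <- simulate_deletions(cfg, seed = 6)
  expect_false(identical(d1, d3))
  expect_true(all(d1$start >= cfg$region$start & d1$stop <= cfg$region$stop))
  expect_true(all(d1$stop - d1$start >= 5e4))
  expect_equal(nrow(simulate_deletions(sim_config(n_patients = 0), 1)), 0L)
  expect_error(sim_config(region = gi("chr2", 100, 200),
                          dl_positions = 5000), "inside")
})

test_that("simulated sizes recover the configured median", {
  d <- simulate_deletions(sim_config(n_patients = 10000), seed = 3)
  med <- stats::median(d$stop - d$start)
  expect_lt(abs(med - 2.39e6) / 2.39e6, 0.05)
})

test_that("phenotypes follow carrier status deterministically at the corners", {
  cfg <- sim_config(p1 = 1, p2 = 1, p_both = 1, f = 0, assess_rate = 1,
                    n_patients = 400)
  sim <- simulate_cohort(cfg, seed = 9)
  carrier <- sim$truth$carrier_status != "none"
  expect_true(all(sim$cohort$sim_trait[carrier] == "+"))
  expect_true(all(sim$cohort$sim_trait[!carrier] == "-"))
  expect_true(all(sim$truth$phenotype_cause[carrier] == "locus"))
})

test_that("both-carrier penetrance converges to the heterogeneity value", {
  cfg <- sim_config(p1 = 0.6, p2 = 0.6, n_patients = 10000)
  sim <- simulate_cohort(cfg, seed = 7)
  both <- sim$truth$carrier_status == "locus1+locus2" &
    sim$cohort$sim_trait != "na"
  k <- sum(sim$cohort$sim_trait[both] == "+")
  n <- sum(both)
  se <- sqrt(cfg$p_both * (1 - cfg$p_both) / n)
  expect_gt(n, 300)
  expect_lt(abs(k / n - cfg$p_both), 3 * se)
})

test_that("SRO recovery finds both loci in phenocopy-free cohorts", {
  cfg <- sim_config(p1 = 0.6, p2 = 0.6, f = 0, n_patients = 200)
  hits <- 0
  for (seed in 1:100) {
    sim <- simulate_cohort(cfg, seed)
    pen <- assessed_subset(sim$cohort, "sim_trait")$penetrant
    s <- identify_sros(pen[, c("patient_id", "chrom", "start", "stop")])
    w1 <- which(s$start <= cfg$dl_positions[1] &
                  cfg$dl_positions[1] < s$stop)
    w2 <- which(s$start <= cfg$dl_positions[2] &
                  cfg$dl_positions[2] < s$stop)
    if (nrow(s) == 2L && length(w1) == 1L && length(w2) == 1L && w1 != w2)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("single-SRO penetrance CIs cover the truth near the nominal rate", {
  cfg <- sim_config(p1 = 0.6, p2 = 0.6, f = 0, n_patients = 200)
  hits <- 0; usable <- 0
  for (seed in 1:100) {
    sim <- simulate_cohort(cfg, seed)
    pen <- assessed_subset(sim$cohort, "sim_trait")$penetrant
    s <- identify_sros(pen[, c("patient_id", "chrom", "start", "stop")])
    pp <- pattern_partition(sim$cohort, "sim_trait", s)
    r1 <- pp[pp$pattern == "SRO1", ]
    if (nrow(r1) != 1L || r1$n == 0) next
    usable <- usable + 1
    if (r1$ci_low <= 0.6 && 0.6 <= r1$ci_high) hits <- hits + 1
  }
  expect_gte(usable, 95)
  expect_gte(hits / usable, 0.85)
})

test_that("one flank phenocopy deletion founds exactly one extra SRO", {
  cfg <- sim_config(p1 = 0.6, p2 = 0.6, f = 0, n_patients = 200)
  sim <- simulate_cohort(cfg, seed = 1)
  pen <- assessed_subset(sim$cohort, "sim_trait")$penetrant
  pen <- pen[, c("patient_id", "chrom", "start", "stop")]
  s0 <- identify_sros(pen)
  # a penetrant deletion left of every stab point: a phenocopy by construction
  phen <- data.frame(patient_id = "phenocopy", chrom = "chr2",
                     start = 55700000, stop = 56200000)
  s1 <- identify_sros(rbind(pen, phen))
  expect_equal(nrow(s1), nrow(s0) + 1L)
  expect_equal(c(s1$start[1], s1$stop[1]), c(phen$start, phen$stop))
})

test_that("epistatic joint penetrance is detected and independence is not", {
  p <- 0.4
  phm <- expected_heterogeneity_penetrance(p, p)
  label_rate <- function(p_both) {
    hits <- 0; usable <- 0
    for (seed in 1:100) {
      cfg <- sim_config(p1 = p, p2 = p, p_both = p_both, n_patients = 200)
      sim <- simulate_cohort(cfg, seed)
      pen <- assessed_subset(sim$cohort, "sim_trait")$penetrant
      s <- try(identify_sros(pen[, c("patient_id", "chrom", "start",
                                     "stop")]), silent = TRUE)
      if (inherits(s, "try-error") || nrow(s) < 2L) next
      pp <- pattern_partition(sim$cohort, "sim_trait", s)
      ia <- try(interaction_assessment(pp), silent = TRUE)
      if (inherits(ia, "try-error")) next
      usable <- usable + 1
      if (ia$label == "suggests_epistasis") hits <- hits + 1
    }
    c(hits = hits, usable = usable)
  }
  pow <- label_rate(min(1, 1.5 * phm))
  expect_gte(pow["usable"], 90)
  expect_gte(pow["hits"] / pow["usable"], 0.90)
  # under independence the strict point comparison flags ~half the seeds;
  # require it within 3 SE of 1/2 (no systematic excess beyond noise)
  null <- label_rate(NULL)
  expect_gte(null["usable"], 90)
  expect_lte(null["hits"] / null["usable"], 0.65)
})

test_that("benchmark files round-trip through the cohort loader", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_patients = 25)
  paths <- generate_benchmark(cfg, dir, seed = 4)
  co <- load_cohort(paths["cohort"])
  expect_equal(nrow(co), 25L)
  expect_equal(trait_names(co), "sim_trait")
  truth <- utils::read.table(paths["truth"], header = TRUE, sep = "\t",
                             comment.char = "#")
  expect_equal(nrow(truth), 25L)
  expect_equal(readLines(paths["cohort"], n = 1L), "# seed: 4")
})
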