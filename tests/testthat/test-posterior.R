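toy_grid <- function(start = 1000, stop = 4000, width = 1000) {
  tile_windows(gi("chr2", start, stop), width = width)
}

test_that("window tiling covers the SRO exactly", {
  g <- toy_grid(1000, 3500)
  expect_equal(nrow(g), 3L)
  expect_equal(g$stop - g$start, c(1000, 1000, 500))
  expect_equal(g$start[1], 1000)
  expect_equal(g$stop[3], 3500)
  expect_equal(nrow(toy_grid(1000, 2000)), 1L)
  # ASD SRO2 has length 105,555 -> 106 windows of 1 kb
  co <- cohort_2p15p16()
  s <- identify_sros(assessed_subset(co, "asd")$penetrant)
  expect_equal(nrow(tile_windows(s[2, ])), 106L)
  expect_error(tile_windows(gi("chr2", 1, 10), width = 0), "width")
})

test_that("window stats equal brute-force overlap counting", {
  co <- cohort_2p15p16()
  s <- identify_sros(assessed_subset(co, "asd")$penetrant)
  g <- tile_windows(s[1, ])
  ws <- window_stats(g, co, "asd")
  expect_true(all(ws$k <= ws$n))
  calls <- co$asd
  rec <- co[calls != "na", ]
  for (j in c(1L, 57L, nrow(g))) {
    w <- g[j, c("chrom", "start", "stop")]
    ov <- gi_overlaps(w, rec[, c("chrom", "start", "stop")])
    expect_equal(ws$n[j], sum(ov))
    expect_equal(ws$k[j], sum(rec$asd[ov] == "+"))
    expect_equal(ws$op[j], sum(rec$asd[ov] == "+") / sum(ov))
  }
  # a window covered by 4 penetrant + 1 non-penetrant has op 0.8
  co4 <- toy_cohort(rep(1000, 5), rep(4000, 5), c(rep("+", 4), "-"))
  ws <- window_stats(toy_grid(), co4, "toy")
  expect_equal(ws$op, rep(0.8, 3))
})

test_that("posterior matches the numeric-integration oracle on a toy case", {
  # penetrant deletion covers windows 1-2; non-penetrant covers window 1
  co <- toy_cohort(c(1000, 1000), c(3000, 2000), c("+", "-"))
  g <- toy_grid()
  s <- identify_sros(assessed_subset(co, "toy")$penetrant)
  prof <- window_posterior(g, co, "toy", s, a = 1, b = 1, f = 0.01)
  ov <- cbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))
  expected <- posterior_oracle(ov, pen = c(TRUE, FALSE), a = 1, b = 1,
                               f = 0.01)
  expect_equal(prof$prob, expected, tolerance = 1e-5)
  expect_equal(which.max(prof$prob), 2L)
  expect_equal(sum(prof$prob), 1, tolerance = 1e-9)
})

test_that("posterior is uniform under fully symmetric evidence", {
  co <- toy_cohort(c(500, 600, 700), c(4200, 4300, 4100), c("+", "+", "-"))
  s <- identify_sros(assessed_subset(co, "toy")$penetrant)
  prof <- window_posterior(toy_grid(), co, "toy", s)
  expect_equal(prof$prob, rep(1 / 3, 3))
})

test_that("posterior normalizes to one on every fixture SRO", {
  co <- cohort_2p15p16()
  for (tr in trait_names(co)) {
    s <- identify_sros(assessed_subset(co, tr)$penetrant)
    for (i in seq_len(nrow(s))) {
      prof <- window_posterior(tile_windows(s[i, ]), co, tr, s)
      expect_equal(sum(prof$prob), 1, tolerance = 1e-9,
                   info = sprintf("%s SRO%d", tr, i))
    }
  }
})

test_that("added non-penetrant evidence on a window never favors it", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    starts <- sample(seq(500, 2000, by = 100), n, replace = TRUE)
    stops <- starts + sample(seq(500, 3500, by = 250), n, replace = TRUE)
    calls <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3))
    calls[1] <- "+"
    co <- toy_cohort(starts, stops, calls)
    s <- identify_sros(assessed_subset(co, "toy")$penetrant)
    g <- tile_windows(s[1, ], width = 500)
    if (nrow(g) < 2L) next
    p0 <- window_posterior(g, co, "toy", s)
    j <- sample(nrow(g), 1)
    co2 <- toy_cohort(c(starts, g$start[j]), c(stops, g$stop[j]),
                      c(calls, "-"))
    p1 <- window_posterior(g, co2, "toy", s)
    untouched <- setdiff(seq_len(nrow(g)), j)
    for (i in untouched) {
      if (p0$prob[i] == 0) next
      expect_lte(p1$prob[j] / p1$prob[i],
                 p0$prob[j] / p0$prob[i] + 1e-12)
    }
  }
})

test_that("f = 0 shrinks support to windows missed by no penetrant deletion", {
  co <- toy_cohort(c(1000, 1500), c(3000, 4000), c("+", "+"))
  s <- gi("chr2", 1000, 4000); s$sro <- 1L
  prof <- window_posterior(tile_windows(s), co, "toy", s, f = 0)
  expect_equal(prof$prob[3], 0)   # window 3 missed by the first deletion
  expect_true(all(prof$prob[1:2] > 0))
  expect_error(window_posterior(tile_windows(s), co, "toy", s, f = 1), "f")
})

test_that("gene cumulative probability sums window mass over gene spans", {
  genes <- data.frame(gene = c("full", "left2", "outside"), chrom = "chr2",
                      start = c(1000, 1000, 9000), stop = c(4000, 3000, 9500),
                      pli = c(1, 0.5, 0))
  co <- toy_cohort(c(1000, 1000), c(3000, 2000), c("+", "-"))
  s <- identify_sros(assessed_subset(co, "toy")$penetrant)
  prof <- window_posterior(toy_grid(), co, "toy", s)
  cp <- gene_cumulative_probability(prof, genes)
  expect_equal(cp$cp[cp$gene == "full"], 1, tolerance = 1e-12)
  expect_equal(cp$cp[cp$gene == "left2"], sum(prof$prob[1:2]))
  expect_equal(cp$cp[cp$gene == "outside"], 0)
})

test_that("XPO1 carries the highest gene probability in the XPO1-region SROs", {
  co <- cohort_2p15p16()
  ge <- gene_table_2p15p16()
  nd <- run_trait(co, ge, "neurodevelopmental_delay")
  for (i in 2:3) {
    cp <- nd$gene_cp[[i]]
    expect_equal(cp$gene[which.max(cp$cp)], "XPO1",
                 info = sprintf("SRO%d", i))
  }
  asd <- run_trait(co, ge, "asd")
  cp2 <- asd$gene_cp[[2]]
  expect_gt(cp2$cp[cp2$gene == "XPO1"], cp2$cp[cp2$gene == "USP34"])
})

test_that("profile export writes one bedGraph record per window", {
  co <- cohort_2p15p16()
  s <- identify_sros(assessed_subset(co, "asd")$penetrant)
  prof <- window_posterior(tile_windows(s[2, ]), co, "asd", s)
  p_log <- withr::local_tempfile(fileext = ".bedgraph")
  p_raw <- withr::local_tempfile(fileext = ".bedgraph")
  export_profile(prof, p_log, p_raw)
  expect_equal(length(readLines(p_log)), 106L)
  vals <- as.numeric(vapply(strsplit(readLines(p_raw), "\t"), `[`, "", 4L))
  expect_equal(sum(vals), 1, tolerance = 1e-6)
  expect_true(all(is.finite(as.numeric(
    vapply(strsplit(readLines(p_log), "\t"), `[`, "", 4L)))))
})
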