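# Shared helpers: toy-cohort builder and independent brute-force oracles.

# builds an sro_cohort directly (same shape load_cohort() returns)
toy_cohort <- function(starts, stops, calls, trait = "toy", chrom = "chr2",
                       ids = sprintf("p%02d", seq_along(starts))) {
  x <- data.frame(patient_id = ids, chrom = chrom, start = starts,
                  stop = stops, stringsAsFactors = FALSE)
  x[[trait]] <- calls
  x$size <- x$stop - x$start
  attr(x, "trait_names") <- trait
  class(x) <- c("sro_cohort", "data.frame")
  x
}

# exhaustive minimum interval-stabbing number (candidate points = stops,
# which always contain an optimal solution for the start < p <= stop rule)
min_stab_bruteforce <- function(x) {
  pts <- sort(unique(x$stop))
  hit1 <- function(p) x$start < p & p <= x$stop
  for (k in seq_along(pts)) {
    combs <- utils::combn(pts, k)
    for (j in seq_len(ncol(combs))) {
      hit <- rep(FALSE, nrow(x))
      for (p in combs[, j, drop = TRUE]) hit <- hit | hit1(p)
      if (all(hit)) return(k)
    }
  }
  stop("unreachable")
}

# random interval set for stabbing properties
random_intervals <- function(n, span = 1000) {
  a <- sort(sample.int(span, n, replace = TRUE))
  b <- a + sample.int(200, n, replace = TRUE)
  data.frame(patient_id = sprintf("r%02d", seq_len(n)), chrom = "chr2",
             start = a, stop = b, stringsAsFactors = FALSE)
}

# numeric-integration oracle for the window posterior: integrates the
# carrier-penetrance Beta prior on a fine grid instead of using lbeta()
posterior_oracle <- function(ov, pen, a = 1, b = 1, f = 0.01,
                             grid_n = 200001) {
  p <- seq(1e-9, 1 - 1e-9, length.out = grid_n)
  m <- vapply(seq_len(ncol(ov)), function(j) {
    carriers <- ov[, j]
    k <- sum(carriers & pen); n <- sum(carriers)
    u <- sum(!carriers & pen); v <- sum(!carriers & !pen)
    integ <- mean(p^k * (1 - p)^(n - k) * stats::dbeta(p, a, b))
    integ * f^u * (1 - f)^v
  }, 0)
  m / sum(m)
}
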