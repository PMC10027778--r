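#' Binomial penetrance estimate with 95% confidence interval
#'
#' Point estimate k/n with a Wilson score interval (default; well behaved at
#' small n and at k = 0 or k = n) or Clopper-Pearson exact interval.
#'
#' @param k penetrant count, `0 <= k <= n`.
#' @param n assessed count, `n >= 1`.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @param conf confidence level (default 0.95).
#' @return list of class `penetrance_estimate`: `k`, `n`, `point`, `ci_low`,
#'   `ci_high`, `method`.
#' @export
penetrance_ci <- function(k, n, method = c("wilson", "clopper-pearson"),
                          conf = 0.95) {
  method <- match.arg(method)
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1) stop("penetrance undefined for n = 0")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    # boundary cases are exact; avoids float residue placing lo above 0
    lo <- if (k == 0) 0 else max(0, centre - half)
    hi <- if (k == n) 1 else min(1, centre + half)
  } else {
    lo <- if (k == 0) 0 else stats::qbeta((1 - conf) / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - (1 - conf) / 2, k + 1, n - k)
  }
  structure(list(k = k, n = n, point = p, ci_low = lo, ci_high = hi,
                 method = method),
            class = "penetrance_estimate")
}

#' @export
print.penetrance_estimate <- function(x, ...) {
  cat(sprintf("%.2f (%d/%d), 95%% CI [%.2f, %.2f] (%s)\n",
              x$point, x$k, x$n, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Expected joint penetrance under the heterogeneity (independence) model
#'
#' For a deletion spanning two disease loci with single-locus penetrances
#' `p1` and `p2`, the probability of being affected through either locus
#' acting independently is `p1 + p2 - p1 * p2` (equivalently
#' `1 - (1 - p1) * (1 - p2)`). Observed joint penetrance above this value
#' suggests epistasis between the loci; at or below it, independence.
#'
#' @param p1,p2 single-locus penetrances in `[0, 1]`.
#' @return the expected joint penetrance.
#' @export
expected_heterogeneity_penetrance <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1))
    stop("penetrances must lie in [0, 1]")
  p1 + p2 - p1 * p2
}

#' Epistasis versus independence for a two-SRO trait
#'
#' Compares the observed penetrance of deletions overlapping both SROs with
#' the heterogeneity-model expectation computed from the exact single-SRO
#' fractions. The label is a point-estimate comparison (ties are called
#' independence, conservatively); an exact binomial tail probability of
#' observing >= k_both penetrant given `p_hm` is reported as descriptive
#' context, not as a decision rule.
#'
#' @param partition output of [pattern_partition()] for a two-SRO trait.
#' @param ci_method CI method passed through to the estimates.
#' @return list of class `interaction_report`: `p_sro1`, `p_sro2`,
#'   `p_both_obs` (penetrance estimates), `p_hm`, `tail_prob`, `label`
#'   (`"suggests_epistasis"` or `"consistent_with_independence"`), `note`.
#' @export
interaction_assessment <- function(partition, ci_method = "wilson") {
  need <- c("SRO1", "SRO2", "all")
  miss <- setdiff(need, partition$pattern[partition$n > 0])
  if (length(miss))
    stop("interaction assessment needs patterns with n >= 1: missing ",
         paste(miss, collapse = ", "))
  row <- function(lv) partition[partition$pattern == lv, ]
  est <- function(lv) penetrance_ci(row(lv)$k, row(lv)$n, method = ci_method)
  p1 <- est("SRO1"); p2 <- est("SRO2"); pb <- est("all")
  p_hm <- expected_heterogeneity_penetrance(p1$point, p2$point)
  label <- if (pb$point > p_hm) "suggests_epistasis" else
    "consistent_with_independence"
  tail_prob <- stats::pbinom(pb$k - 1, pb$n, p_hm, lower.tail = FALSE)
  structure(list(
    p_sro1 = p1, p_sro2 = p2, p_both_obs = pb, p_hm = p_hm,
    tail_prob = tail_prob, label = label,
    note = sprintf(
      "observed both-SRO penetrance %.2f (%d/%d) vs heterogeneity expectation %.2f; P(X >= %d | n = %d, p_hm) = %.3f",
      pb$point, pb$k, pb$n, p_hm, pb$k, pb$n, tail_prob)),
    class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat(sprintf("SRO1 %.2f (%d/%d)  SRO2 %.2f (%d/%d)  both %.2f (%d/%d)\n",
              x$p_sro1$point, x$p_sro1$k, x$p_sro1$n,
              x$p_sro2$point, x$p_sro2$k, x$p_sro2$n,
              x$p_both_obs$point, x$p_both_obs$k, x$p_both_obs$n))
  cat(sprintf("p_hm = %.2f -> %s\n", x$p_hm, x$label))
  invisible(x)
}

#' Penetrance by driver-gene hemizygosity group
#'
#' Classifies each deletion by which driver-gene sets it overlaps and reports
#' per-trait penetrance with 95% CI per group. The default grouping contrasts
#' deletions affecting only the first gene set, only the second, or both --
#' e.g. BCL11A alone vs USP34/XPO1 alone vs all three.
#'
#' @param cohort an `sro_cohort`.
#' @param traits character vector of trait names.
#' @param genes gene table (see [read_gene_table()]).
#' @param set1,set2 gene symbols defining the two driver sets (defaults
#'   `"BCL11A"` and `c("USP34", "XPO1")`).
#' @param ci_method CI method.
#' @return data.frame: `group`, `trait`, `k`, `n`, `point`, `ci_low`,
#'   `ci_high`. Groups: `set1_only`, `set2_only`, `both`, `neither`.
#' @export
gene_group_penetrance <- function(cohort, traits, genes,
                                  set1 = "BCL11A",
                                  set2 = c("USP34", "XPO1"),
                                  ci_method = "wilson") {
  miss <- setdiff(c(set1, set2), genes$gene)
  if (length(miss))
    stop("gene(s) absent from gene table: ", paste(miss, collapse = ", "))
  for (tr in traits) check_trait(cohort, tr)
  hits_set <- function(del, set) {
    g <- genes[genes$gene %in% set, , drop = FALSE]
    any(vapply(seq_len(nrow(g)), function(j)
      gi_overlaps(g[j, c("chrom", "start", "stop")],
                  del[, c("chrom", "start", "stop")]), NA))
  }
  grp <- vapply(seq_len(nrow(cohort)), function(i) {
    del <- cohort[i, , drop = FALSE]
    h1 <- hits_set(del, set1); h2 <- hits_set(del, set2)
    if (h1 && h2) "both" else if (h1) "set1_only" else if (h2) "set2_only"
    else "neither"
  }, "")
  out <- expand.grid(group = c("set1_only", "set2_only", "both", "neither"),
                     trait = traits, stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    in_grp <- grp == out$group[i]
    calls <- cohort[[out$trait[i]]][in_grp]
    n <- sum(calls != "na"); k <- sum(calls == "+")
    if (n == 0L)
      return(data.frame(out[i, ], k = 0L, n = 0L, point = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    est <- penetrance_ci(k, n, method = ci_method)
    data.frame(out[i, ], k = k, n = n, point = est$point,
               ci_low = est$ci_low, ci_high = est$ci_high)
  }))
  res <- res[res$n > 0 | res$group != "neither", ]
  rownames(res) <- NULL
  res
}
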