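#' Tile an SRO with non-overlapping windows
#'
#' @param sro a single-row interval data frame (typically one row of an
#'   `sro_set`).
#' @param width window width in bases (default 1000); the final window may be
#'   shorter.
#' @return data.frame of class `window_grid` with `chrom`, `start`, `stop`,
#'   one row per window, covering the SRO exactly; the source interval and
#'   SRO index (if any) are kept in attributes `region` and `sro`.
#' @export
tile_windows <- function(sro, width = 1000) {
  stopifnot(nrow(sro) == 1L)
  if (width < 1) stop("window width must be >= 1")
  len <- sro$stop - sro$start
  m <- ceiling(len / width)
  starts <- sro$start + (seq_len(m) - 1L) * width
  g <- data.frame(chrom = sro$chrom, start = starts,
                  stop = pmin(starts + width, sro$stop))
  attr(g, "region") <- sro[, c("chrom", "start", "stop")]
  if ("sro" %in% names(sro)) attr(g, "sro") <- sro$sro
  class(g) <- c("window_grid", "data.frame")
  g
}

# records x windows overlap matrix under the shared-base rule
overlap_matrix <- function(records, grid) {
  outer(seq_len(nrow(records)), seq_len(nrow(grid)),
        function(i, j) records$chrom[i] == grid$chrom[j] &
          records$start[i] < grid$stop[j] & grid$start[j] < records$stop[i])
}

#' Observed penetrance per window
#'
#' For each window: n = assessed deletions overlapping the window, k =
#' penetrant among them, op = k/n (NA when no deletion covers the window).
#'
#' @param grid a `window_grid`.
#' @param cohort an `sro_cohort`.
#' @param trait trait name.
#' @return data.frame: window coordinates plus `n`, `k`, `op`.
#' @export
window_stats <- function(grid, cohort, trait) {
  check_trait(cohort, trait)
  calls <- cohort[[trait]]
  rec <- cohort[calls != "na", , drop = FALSE]
  pen <- calls[calls != "na"] == "+"
  ov <- overlap_matrix(rec, grid)
  n <- colSums(ov)
  k <- colSums(ov & pen)
  data.frame(grid[, c("chrom", "start", "stop")], n = n, k = k,
             op = ifelse(n > 0, k / n, NA_real_))
}

#' Posterior probability that each window contains the disease locus
#'
#' Beta-binomial carrier model: the SRO is assumed to contain exactly one
#' disease locus (DL), uniform over windows a priori. Conditional on the DL
#' lying in window j, the deletions overlapping the SRO (the evidence set)
#' split into carriers (overlap window j; their unknown carrier penetrance
#' gets a Beta(a, b) prior, integrated out as a Beta-binomial marginal) and
#' non-carriers, whose trait status is explained by the phenocopy rate `f`:
#' a penetrant deletion missing window j contributes a factor `f`, a
#' non-penetrant one `1 - f`. Posterior probabilities are normalized to sum
#' to 1 within the SRO, which by construction contains the DL.
#'
#' With `explain_other_sros = TRUE`, penetrant deletions that miss window j
#' but overlap another SRO of the same trait contribute a factor 1 instead of
#' `f` (their phenotype attributed to the other locus). The default `FALSE`
#' penalizes every penetrant miss, which concentrates mass where penetrant
#' coverage is deepest and, on the bundled cohort, ranks the genes the way
#' the trait analyses report.
#'
#' @param grid a `window_grid` tiling one SRO.
#' @param cohort an `sro_cohort`.
#' @param trait trait name.
#' @param sros the trait's full `sro_set` (used to identify the other SROs).
#' @param a,b Beta prior parameters for carrier penetrance (default 1, 1).
#' @param f phenocopy rate in `[0, 1)`; default 0.01. `f = 0` is allowed and
#'   shrinks support to windows missed by no penetrant deletion.
#' @param explain_other_sros see Details.
#' @return data.frame of class `posterior_profile`: window coordinates,
#'   `n`, `k`, `op`, `prob`, `log10_prob`; model parameters in
#'   `attr(, "params")`.
#' @export
window_posterior <- function(grid, cohort, trait, sros, a = 1, b = 1,
                             f = 0.01, explain_other_sros = FALSE) {
  check_trait(cohort, trait)
  if (f < 0 || f >= 1) stop("phenocopy rate f must lie in [0, 1)")
  if (a <= 0 || b <= 0) stop("Beta prior parameters must be positive")
  region <- attr(grid, "region")
  calls <- cohort[[trait]]
  rec <- cohort[calls != "na", , drop = FALSE]
  pen <- calls[calls != "na"] == "+"
  in_evidence <- gi_overlaps(region, rec[, c("chrom", "start", "stop")])
  if (!any(in_evidence))
    stop("no assessed deletion overlaps the SRO: evidence set is empty")
  rec <- rec[in_evidence, , drop = FALSE]
  pen <- pen[in_evidence]
  ov <- overlap_matrix(rec, grid)            # evidence x windows
  n <- colSums(ov)
  k <- colSums(ov & pen)
  exempt <- rep(FALSE, nrow(rec))
  if (explain_other_sros && nrow(sros) > 1L) {
    others <- sros[!(sros$start == region$start &
                       sros$stop == region$stop), , drop = FALSE]
    if (nrow(others))
      exempt <- vapply(seq_len(nrow(rec)), function(i)
        any(gi_overlaps(rec[i, c("chrom", "start", "stop")],
                        others[, c("chrom", "start", "stop")])), NA)
  }
  u <- colSums((!ov) & pen & !exempt)        # penetrant misses, penalized
  v <- colSums((!ov) & !pen)                 # non-penetrant misses
  miss_term <- if (f == 0) ifelse(u > 0, -Inf, 0) else u * log(f)
  log_m <- lbeta(k + a, n - k + b) - lbeta(a, b) + miss_term + v * log1p(-f)
  if (all(!is.finite(log_m)))
    stop("posterior degenerate: every window is missed by some penetrant deletion and f = 0")
  log_m <- log_m - max(log_m[is.finite(log_m)])
  w <- exp(log_m)
  probs <- w / sum(w)
  out <- data.frame(grid[, c("chrom", "start", "stop")], n = n, k = k,
                    op = ifelse(n > 0, k / n, NA_real_), prob = probs,
                    log10_prob = pmax(log10(pmax(probs, 0)), -300))
  attr(out, "region") <- region
  attr(out, "sro") <- attr(grid, "sro")
  attr(out, "params") <- list(a = a, b = b, f = f,
                              explain_other_sros = explain_other_sros)
  class(out) <- c("posterior_profile", "data.frame")
  out
}

#' Cumulative probability per gene
#'
#' cp(gene) = sum of window posterior probabilities over windows sharing at
#' least one base with the gene span, within one SRO.
#'
#' @param profile a `posterior_profile`.
#' @param genes gene table (see [read_gene_table()]).
#' @return data.frame: `gene`, `pli`, `cp`, sorted by cp descending.
#' @export
gene_cumulative_probability <- function(profile, genes) {
  cp <- vapply(seq_len(nrow(genes)), function(j)
    sum(profile$prob[gi_overlaps(genes[j, c("chrom", "start", "stop")],
                                 profile[, c("chrom", "start", "stop")])]),
    0)
  out <- data.frame(gene = genes$gene, pli = genes$pli, cp = cp,
                    stringsAsFactors = FALSE)
  out[order(-out$cp, out$gene), ]
}

#' Export a posterior profile as bedGraph tracks
#'
#' Writes one record per window: `path_log` carries log10 posterior
#' probability (floored at -300 so browsers accept the file), and, when
#' given, `path_raw` carries the raw probabilities.
#'
#' @param profile a `posterior_profile`.
#' @param path_log output path for the log10 track.
#' @param path_raw optional output path for the raw-probability track.
#' @param track optional track name.
#' @return `path_log`, invisibly.
#' @export
export_profile <- function(profile, path_log, path_raw = NULL, track = NULL) {
  g <- profile[, c("chrom", "start", "stop")]
  write_bedgraph(g, profile$log10_prob, path_log, track = track)
  if (!is.null(path_raw))
    write_bedgraph(g, profile$prob, path_raw, track = track)
  invisible(path_log)
}
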