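#' Delineate Shortest Regions of Overlap from penetrant deletions
#'
#' Greedy minimal interval stabbing (earliest-end rule), which is optimal for
#' one-dimensional interval piercing: deletions are sorted by stop ascending
#' (ties by start, then patient id); the uncovered deletion with the smallest
#' stop donates its stop as a stab point; all deletions containing that point
#' (`start < p <= stop`) are marked covered; repeat until every penetrant
#' deletion is covered. By construction every penetrant deletion contains at
#' least one stab point, so each SRO has probability 1 of containing the
#' disease locus of the deletions it explains.
#'
#' Each SRO's region is the intersection of the penetrant deletions that
#' contain its stab point and no other stab point. Deletions spanning several
#' stab points are compatible with any one of the corresponding loci driving
#' their phenotype, so they carry no localizing information for an individual
#' SRO and are excluded from its delineation (they remain in the `stabbed`
#' count and in all penetrance denominators).
#'
#' @param deletions data.frame with `patient_id`, `chrom`, `start`, `stop`
#'   (one chromosome), each row a trait-penetrant deletion.
#' @return data.frame of class `sro_set`, one row per SRO sorted by genomic
#'   position and 1-indexed: columns `sro`, `chrom`, `start`, `stop`,
#'   `stab_point`, `n_members`, `n_stabbed`, plus list columns `members`
#'   (patient ids defining the region) and `stabbed` (all penetrant patient
#'   ids containing the stab point).
#' @export
identify_sros <- function(deletions) {
  if (is.null(deletions) || nrow(deletions) == 0L)
    stop("no penetrant deletions: SROs undefined")
  if (!"patient_id" %in% names(deletions))
    deletions$patient_id <- sprintf("del_%d", seq_len(nrow(deletions)))
  validate_gi(deletions)
  if (length(unique(deletions$chrom)) != 1L)
    stop("SRO delineation requires a single chromosome")
  d <- deletions[order(deletions$stop, deletions$start, deletions$patient_id), ]
  covered <- rep(FALSE, nrow(d))
  stabs <- numeric(0)
  while (!all(covered)) {
    p <- d$stop[which(!covered)[1L]]
    stabs <- c(stabs, p)
    covered <- covered | gi_stabs(d, p)
  }
  n_stab_points <- vapply(seq_len(nrow(d)), function(i)
    sum(d$start[i] < stabs & stabs <= d$stop[i]), 0L)
  out <- lapply(sort(stabs), function(p) {
    hit <- gi_stabs(d, p)
    member <- hit & n_stab_points == 1L
    region <- gi_intersect_all(d[member, c("chrom", "start", "stop")])
    data.frame(chrom = region$chrom, start = region$start, stop = region$stop,
               stab_point = p,
               n_members = sum(member), n_stabbed = sum(hit),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(sro = seq_len(nrow(res)), res)
  res$members <- lapply(sort(stabs), function(p)
    d$patient_id[gi_stabs(d, p) & n_stab_points == 1L])
  res$stabbed <- lapply(sort(stabs), function(p) d$patient_id[gi_stabs(d, p)])
  class(res) <- c("sro_set", "data.frame")
  res
}

#' SRO-overlap pattern of one deletion
#'
#' @param deletion single-row interval data frame.
#' @param sros an `sro_set`.
#' @return integer vector of SRO indices sharing >= 1 base with the deletion
#'   (possibly empty).
#' @export
overlap_pattern <- function(deletion, sros) {
  stopifnot(nrow(deletion) == 1L)
  sros$sro[gi_overlaps(deletion, sros)]
}

pattern_label <- function(idx, n_sro) {
  if (length(idx) == 0L) return("none")
  if (length(idx) == n_sro && n_sro > 1L) return("all")
  paste(sprintf("SRO%d", sort(idx)), collapse = "+")
}

#' Penetrance by SRO-overlap pattern
#'
#' Groups the assessed deletions of a trait by which SROs they overlap
#' (completely or partially) and reports k penetrant of n assessed per group.
#' For a two-SRO trait the groups are `SRO1`, `SRO2`, `all` (both) and
#' possibly `none`; deletions overlapping no SRO are reported, not dropped.
#'
#' @param cohort an `sro_cohort`.
#' @param trait trait name.
#' @param sros the trait's `sro_set` (from [identify_sros()] on the trait's
#'   penetrant deletions).
#' @param ci_method CI method for the per-group estimate.
#' @return data.frame: `pattern`, `k`, `n`, `point`, `ci_low`, `ci_high`,
#'   ordered single SROs first, then multi-SRO patterns, then `none`.
#' @export
pattern_partition <- function(cohort, trait, sros, ci_method = "wilson") {
  check_trait(cohort, trait)
  calls <- cohort[[trait]]
  keep <- calls != "na"
  rec <- cohort[keep, , drop = FALSE]
  pen <- calls[keep] == "+"
  n_sro <- nrow(sros)
  pat <- vapply(seq_len(nrow(rec)), function(i)
    pattern_label(overlap_pattern(rec[i, c("chrom", "start", "stop")], sros),
                  n_sro), "")
  lev <- unique(c(sprintf("SRO%d", seq_len(n_sro)),
                  sort(setdiff(pat, c(sprintf("SRO%d", seq_len(n_sro)),
                                      "all", "none"))),
                  "all", "none"))
  lev <- lev[lev %in% pat]
  out <- do.call(rbind, lapply(lev, function(lv) {
    k <- sum(pen[pat == lv]); n <- sum(pat == lv)
    est <- if (n > 0L) penetrance_ci(k, n, method = ci_method) else
      list(point = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    data.frame(pattern = lv, k = k, n = n, point = est$point,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
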