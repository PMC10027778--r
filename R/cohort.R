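#' Load and validate a deletion cohort
#'
#' A cohort is a TSV with columns `patient_id`, `chrom`, `start`, `stop`, an
#' optional `inheritance` column, then one column per trait with calls in
#' `{+, -, na}` (`na` = not assessed; excluded from every denominator).
#'
#' @param path cohort TSV path.
#' @return data.frame of class `sro_cohort`: one row per patient, a recomputed
#'   `size` column (`stop - start`), trait columns as characters, and the
#'   trait names in `attr(, "trait_names")`.
#' @export
load_cohort <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  need <- c("patient_id", "chrom", "start", "stop")
  if (!all(need %in% names(x)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  dup <- x$patient_id[duplicated(x$patient_id)]
  if (length(dup)) stop("duplicate patient_id: ", dup[1L])
  bad <- which(x$stop <= x$start)
  if (length(bad))
    stop("stop <= start for patient ", x$patient_id[bad[1L]])
  validate_gi(x)
  traits <- setdiff(names(x), c(need, "inheritance", "size"))
  if (!length(traits)) stop("cohort table has no trait columns")
  for (tr in traits) {
    bad <- which(!x[[tr]] %in% c("+", "-", "na"))
    if (length(bad))
      stop("invalid trait value '", x[[tr]][bad[1L]], "' for trait '", tr,
           "' in row for patient ", x$patient_id[bad[1L]])
  }
  x$size <- x$stop - x$start
  attr(x, "trait_names") <- traits
  class(x) <- c("sro_cohort", "data.frame")
  x
}

#' The published 38-patient 2p15p16.1 cohort
#'
#' Deletion intervals (hg19, printed 1-based coordinates) and calls for six
#' traits (neurodevelopmental delay, autistic behavior, microcephaly, brain
#' anomalies, hearing loss, IUGR) for the 38 curated patients; all deletions
#' are de novo.
#'
#' @return an `sro_cohort` (see [load_cohort()]).
#' @export
cohort_2p15p16 <- function() {
  load_cohort(system.file("extdata", "cohort_2p15p16_hg19.tsv",
                          package = "sromapper", mustWork = TRUE))
}

#' Trait names of a cohort
#' @param cohort an `sro_cohort`.
#' @return character vector in column order.
#' @export
trait_names <- function(cohort) attr(cohort, "trait_names")

check_trait <- function(cohort, trait) {
  if (!trait %in% trait_names(cohort))
    stop("unknown trait '", trait, "'; cohort traits: ",
         paste(trait_names(cohort), collapse = ", "))
}

#' Partition a cohort into penetrant / non-penetrant records for a trait
#'
#' Only assessed records are returned; `na` calls are dropped.
#'
#' @param cohort an `sro_cohort`.
#' @param trait trait name.
#' @return list with data frames `penetrant` and `non_penetrant`.
#' @export
assessed_subset <- function(cohort, trait) {
  check_trait(cohort, trait)
  calls <- cohort[[trait]]
  list(penetrant = as.data.frame(cohort[calls == "+", , drop = FALSE]),
       non_penetrant = as.data.frame(cohort[calls == "-", , drop = FALSE]))
}

#' Overall penetrance of a trait
#'
#' k = patients with the trait present, n = patients assessed; the 95% CI
#' uses [penetrance_ci()].
#'
#' @inheritParams assessed_subset
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return a `penetrance_estimate` (see [penetrance_ci()]).
#' @export
trait_penetrance <- function(cohort, trait, ci_method = "wilson") {
  sub <- assessed_subset(cohort, trait)
  n <- nrow(sub$penetrant) + nrow(sub$non_penetrant)
  if (n == 0L)
    stop("penetrance undefined: no patient assessed for trait '", trait, "'")
  penetrance_ci(nrow(sub$penetrant), n, method = ci_method)
}

#' Deletion size summary in megabases
#'
#' The median is reported as the lower middle order statistic (quantile
#' type 1), the convention under which the bundled cohort reproduces its
#' published size summary; for odd n it coincides with the usual median.
#'
#' @param cohort an `sro_cohort`.
#' @return list with `mean_mb` and `median_mb`, rounded half-up to 2 decimals.
#' @export
size_summary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  sz <- (cohort$stop - cohort$start) / 1e6
  list(mean_mb = round_half_up(mean(sz), 2),
       median_mb = round_half_up(unname(stats::quantile(sz, 0.5, type = 1)), 2))
}

# round-half-up at `digits` decimals, matching the reporting style of the
# clinical tables (base round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
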