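#' Configuration for a synthetic deletion cohort
#'
#' Emulates the structure of a curated microdeletion case series: one
#' deletion per patient over a multi-megabase region, one or two hidden
#' disease loci (DLs) with per-locus carrier penetrances, a phenocopy rate
#' for non-carriers, and partial trait assessment. Deletion lengths follow a
#' log-normal law parameterized by its median (default 2.39 Mb, the bundled
#' cohort's median) truncated to `[50 kb, region length]`; midpoints are
#' uniform over the region and intervals are clipped to it.
#'
#' @param region single-row interval data frame (default chr2:55,616,146-
#'   66,376,960, the bundled cohort's span).
#' @param n_patients number of simulated patients.
#' @param dl_positions one or two DL base positions inside the region. The
#'   default places two loci 4 Mb apart: SRO recovery degrades when locus
#'   separation is comparable to the typical deletion size, because carriers
#'   of one locus then routinely bridge into the other locus's stab group.
#' @param p1,p2 carrier penetrance of DL1 (and DL2 when present).
#' @param p_both penetrance for carriers of both DLs; default `NULL` means
#'   the heterogeneity-model value `p1 + p2 - p1 * p2` (independence).
#' @param f phenocopy rate: trait probability for non-carriers (default 0.01).
#' @param assess_rate probability a patient is assessed for the trait.
#' @param size_median_bp,size_sdlog log-normal deletion-size parameters.
#' @param trait simulated trait column name.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(region = gi("chr2", 55616146, 66376960),
                       n_patients = 200,
                       dl_positions = c(58500000, 62500000),
                       p1 = 0.6, p2 = 0.6, p_both = NULL,
                       f = 0.01, assess_rate = 1,
                       size_median_bp = 2.39e6, size_sdlog = 0.5,
                       trait = "sim_trait") {
  stopifnot(nrow(region) == 1L)
  if (region$stop - region$start < 2)
    stop("degenerate region")
  if (any(dl_positions <= region$start | dl_positions >= region$stop))
    stop("disease-locus positions must lie inside the region")
  if (length(dl_positions) < 1L || length(dl_positions) > 2L)
    stop("one or two disease loci supported")
  if (is.null(p_both)) p_both <- expected_heterogeneity_penetrance(p1, p2)
  probs <- c(p1, p2, p_both, f, assess_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(region = region, n_patients = n_patients,
                 dl_positions = dl_positions, p1 = p1, p2 = p2,
                 p_both = p_both, f = f, assess_rate = assess_rate,
                 size_median_bp = size_median_bp, size_sdlog = size_sdlog,
                 trait = trait),
            class = "sim_config")
}

#' Simulate deletion intervals
#'
#' @param config a `sim_config`.
#' @param seed integer seed; all draws are reproducible from it.
#' @return data.frame: `patient_id`, `chrom`, `start`, `stop`.
#' @export
simulate_deletions <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients
  if (n == 0L)
    return(data.frame(patient_id = character(), chrom = character(),
                      start = numeric(), stop = numeric()))
  r <- config$region
  reg_len <- r$stop - r$start
  len <- stats::rlnorm(n, meanlog = log(config$size_median_bp),
                       sdlog = config$size_sdlog)
  len <- pmin(pmax(round(len), 5e4), reg_len)
  # midpoint uniform over the sub-range where the deletion fits, so the
  # realized size equals the drawn size (boundary clipping would otherwise
  # bias the size distribution low)
  lo <- r$start + len / 2
  hi <- r$stop - len / 2
  mid <- lo + stats::runif(n) * pmax(hi - lo, 0)
  start <- pmax(round(mid - len / 2), r$start)
  stop <- pmin(round(mid + len / 2), r$stop)
  stop <- pmax(stop, start + 1)
  data.frame(patient_id = sprintf("sim_%04d", seq_len(n)),
             chrom = r$chrom, start = start, stop = stop,
             stringsAsFactors = FALSE)
}

# half-open coverage of a point, consistent with gi_stabs on the last base
covers_point <- function(x, pos) x$start <= pos & pos < x$stop

#' Assign phenotypes given the hidden disease-locus architecture
#'
#' Carrier status is which DL positions the deletion covers; the trait is
#' present with probability `p1`, `p2`, `p_both` or `f` accordingly, and the
#' record is not assessed with probability `1 - assess_rate`.
#'
#' @param deletions output of [simulate_deletions()].
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list with `cohort` (an `sro_cohort`) and `truth` (data.frame:
#'   `patient_id`, `carrier_status`, `phenotype_cause`).
#' @export
assign_phenotypes <- function(deletions, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed + 1L)
  n <- nrow(deletions)
  dls <- config$dl_positions
  c1 <- covers_point(deletions, dls[1L])
  c2 <- if (length(dls) == 2L) covers_point(deletions, dls[2L]) else
    rep(FALSE, n)
  p_trait <- ifelse(c1 & c2, config$p_both,
                    ifelse(c1, config$p1,
                           ifelse(c2, config$p2, config$f)))
  present <- stats::runif(n) < p_trait
  assessed <- stats::runif(n) < config$assess_rate
  call <- ifelse(!assessed, "na", ifelse(present, "+", "-"))
  cohort <- deletions
  cohort$inheritance <- "simulated"
  cohort[[config$trait]] <- call
  cohort$size <- cohort$stop - cohort$start
  attr(cohort, "trait_names") <- config$trait
  class(cohort) <- c("sro_cohort", "data.frame")
  status <- ifelse(c1 & c2, "locus1+locus2",
                   ifelse(c1, "locus1", ifelse(c2, "locus2", "none")))
  cause <- ifelse(!present, "none",
                  ifelse(c1 | c2, "locus", "phenocopy"))
  truth <- data.frame(patient_id = deletions$patient_id,
                      carrier_status = status, phenotype_cause = cause,
                      assessed = assessed, stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Simulate a full cohort in one call
#'
#' @inheritParams assign_phenotypes
#' @return as [assign_phenotypes()].
#' @export
simulate_cohort <- function(config, seed = 1L) {
  assign_phenotypes(simulate_deletions(config, seed), config, seed)
}

#' Write a synthetic benchmark to disk
#'
#' Writes the cohort in the exact [load_cohort()] dialect plus a truth
#' sidecar; both files carry the seed in a `#` header line.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, named paths `cohort` and `truth`.
#' @export
generate_benchmark <- function(config, dir, seed = 1L) {
  sim <- simulate_cohort(config, seed)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             truth = file.path(dir, "truth.tsv"))
  hdr <- sprintf("# seed: %d", seed)
  cohort <- sim$cohort[, c("patient_id", "chrom", "start", "stop",
                           "inheritance", config$trait)]
  writeLines(c(hdr, paste(names(cohort), collapse = "\t")), paths["cohort"])
  utils::write.table(cohort, paths["cohort"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  writeLines(c(hdr, paste(names(sim$truth), collapse = "\t")), paths["truth"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(paths)
}
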