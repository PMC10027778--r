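#' Run the full per-trait analysis
#'
#' Executes the whole chain for one trait: assessed-subset split, SRO
#' delineation from the penetrant deletions, per-SRO window posterior and
#' per-gene cumulative probabilities, SRO-overlap pattern penetrance, and
#' (for two-SRO traits) the heterogeneity-model interaction assessment.
#' When `out_dir` is given, writes the report bundle: SRO BED track,
#' per-SRO bedGraph posterior tracks (raw and log10), window-stats TSV,
#' gene-cp TSV, pattern-penetrance TSV and a JSON summary.
#'
#' @param cohort an `sro_cohort`.
#' @param genes gene table (see [read_gene_table()]).
#' @param trait trait name.
#' @param out_dir optional output directory.
#' @param window window width in bases (default 1000).
#' @param a,b,f,explain_other_sros posterior parameters, see
#'   [window_posterior()].
#' @param ci_method CI method for penetrance estimates.
#' @return list of class `trait_report`: `trait`, `overall` (penetrance
#'   estimate), `sros` (`sro_set` or `NULL`), `sro_genes` (per-SRO gene
#'   annotation), `profiles` (list of `posterior_profile`), `gene_cp`
#'   (per-SRO cp tables), `partition`, `interaction` (or `NULL`), `params`,
#'   `manifest` (written paths).
#' @export
run_trait <- function(cohort, genes, trait, out_dir = NULL, window = 1000,
                      a = 1, b = 1, f = 0.01, explain_other_sros = FALSE,
                      ci_method = "wilson") {
  check_trait(cohort, trait)
  params <- list(window = window, a = a, b = b, f = f,
                 explain_other_sros = explain_other_sros,
                 ci_method = ci_method)
  sub <- assessed_subset(cohort, trait)
  if (nrow(sub$penetrant) + nrow(sub$non_penetrant) == 0L)
    stop("no patient assessed for trait '", trait, "'")
  overall <- trait_penetrance(cohort, trait, ci_method)
  if (nrow(sub$penetrant) == 0L) {
    warning("no penetrant deletions for trait '", trait,
            "': no SRO can be delineated")
    return(structure(list(trait = trait, overall = overall, sros = NULL,
                          sro_genes = NULL, profiles = NULL, gene_cp = NULL,
                          partition = NULL, interaction = NULL,
                          params = params, manifest = character()),
                     class = "trait_report"))
  }
  sros <- identify_sros(sub$penetrant[, c("patient_id", "chrom", "start",
                                          "stop")])
  sro_genes <- lapply(seq_len(nrow(sros)), function(i)
    genes$gene[gi_overlaps(sros[i, c("chrom", "start", "stop")],
                           genes[, c("chrom", "start", "stop")])])
  names(sro_genes) <- sprintf("SRO%d", sros$sro)
  profiles <- list(); gene_cp <- list()
  for (i in seq_len(nrow(sros))) {
    grid <- tile_windows(sros[i, ], width = window)
    prof <- window_posterior(grid, cohort, trait, sros, a = a, b = b, f = f,
                             explain_other_sros = explain_other_sros)
    profiles[[i]] <- prof
    gi_cp <- gene_cumulative_probability(prof, genes)
    gene_cp[[i]] <- cbind(sro = sros$sro[i], gi_cp[gi_cp$cp > 0, ])
  }
  partition <- pattern_partition(cohort, trait, sros, ci_method)
  interaction <- NULL
  if (nrow(sros) == 2L &&
      all(c("SRO1", "SRO2", "all") %in% partition$pattern[partition$n > 0]))
    interaction <- interaction_assessment(partition, ci_method)
  report <- structure(list(trait = trait, overall = overall, sros = sros,
                           sro_genes = sro_genes, profiles = profiles,
                           gene_cp = gene_cp, partition = partition,
                           interaction = interaction, params = params,
                           manifest = character()),
                      class = "trait_report")
  if (!is.null(out_dir)) report <- write_trait_report(report, out_dir)
  report
}

write_trait_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  tr <- report$trait
  paths <- character()
  pth <- function(name) file.path(out_dir, sprintf("%s_%s", tr, name))
  sros <- report$sros
  p <- pth("sros.bed")
  write_bed(sros[, c("chrom", "start", "stop")],
            sprintf("SRO%d", sros$sro), p, track = paste0(tr, "_SROs"))
  paths <- c(paths, p)
  for (i in seq_along(report$profiles)) {
    prof <- report$profiles[[i]]
    p_log <- pth(sprintf("sro%d_posterior_log10.bedgraph", i))
    p_raw <- pth(sprintf("sro%d_posterior.bedgraph", i))
    export_profile(prof, p_log, p_raw,
                   track = sprintf("%s_SRO%d_posterior", tr, i))
    p_op <- pth(sprintf("sro%d_window_stats.tsv", i))
    write_tsv(as.data.frame(prof), p_op)
    paths <- c(paths, p_log, p_raw, p_op)
  }
  cp_all <- do.call(rbind, report$gene_cp)
  p <- pth("gene_cp.tsv"); write_tsv(cp_all, p); paths <- c(paths, p)
  p <- pth("pattern_penetrance.tsv")
  write_tsv(report$partition, p); paths <- c(paths, p)
  summary <- list(trait = tr,
                  overall = unclass(report$overall),
                  n_sros = nrow(sros),
                  sros = cbind(sros[, c("sro", "chrom", "start", "stop",
                                        "stab_point", "n_members")],
                               genes = vapply(report$sro_genes, paste,
                                              "", collapse = ",")),
                  params = report$params)
  if (!is.null(report$interaction))
    summary$interaction <- list(
      p_hm = report$interaction$p_hm,
      label = report$interaction$label,
      tail_prob = report$interaction$tail_prob)
  p <- pth("summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  paths <- c(paths, p)
  report$manifest <- paths
  report
}

write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, NA)
  x[num] <- lapply(x[num], function(v)
    ifelse(is.na(v), "NA", format(v, trim = TRUE, digits = 12,
                                  scientific = FALSE)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @export
print.trait_report <- function(x, ...) {
  cat(sprintf("Trait: %s  overall penetrance %.2f (%d/%d)\n", x$trait,
              x$overall$point, x$overall$k, x$overall$n))
  if (is.null(x$sros)) {
    cat("No penetrant deletions: no SRO delineated.\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$sros)))
    cat(sprintf("  SRO%d %s:%s-%s  genes: %s\n", x$sros$sro[i],
                x$sros$chrom[i], format_pos(x$sros$start[i]),
                format_pos(x$sros$stop[i]),
                paste(x$sro_genes[[i]], collapse = ", ")))
  if (!is.null(x$interaction)) print(x$interaction)
  invisible(x)
}

#' Run all traits and write the cross-trait summary
#'
#' @inheritParams run_trait
#' @param traits character vector of trait names (default: all cohort traits).
#' @param out_dir output directory for the per-trait bundles and the
#'   cross-trait `penetrance_summary.tsv`.
#' @param ... further arguments passed to [run_trait()].
#' @return named list of `trait_report`s, invisibly; attribute `summary`
#'   holds the cross-trait penetrance table.
#' @export
run_all <- function(cohort, genes, traits = trait_names(cohort),
                    out_dir = NULL, ...) {
  if (!length(traits)) stop("empty trait list")
  reports <- lapply(traits, function(tr) {
    tryCatch(run_trait(cohort, genes, tr, out_dir = out_dir, ...),
             error = function(e)
               stop("trait '", tr, "' failed: ", conditionMessage(e)))
  })
  names(reports) <- traits
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(trait = r$trait, k = r$overall$k, n = r$overall$n,
               penetrance = round_half_up(r$overall$point, 2),
               n_sros = if (is.null(r$sros)) 0L else nrow(r$sros))))
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    write_tsv(summary, file.path(out_dir, "penetrance_summary.tsv"))
  attr(reports, "summary") <- summary
  invisible(reports)
}
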