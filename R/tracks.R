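#' Write a 4-column BED track
#'
#' Converts printed 1-based coordinates to the UCSC 0-based half-open dialect:
#' output start = printed start - 1, output end = printed stop. An optional
#' `track` header line is prepended so the file loads in a genome browser
#' unmodified.
#'
#' @param x interval data frame (see [gi()]), sorted by start.
#' @param names character vector of feature names.
#' @param path output file path.
#' @param scores optional numeric scores (BED column 5); omitted when `NULL`.
#' @param track optional track name; written as a `track name=... ` header.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, names, path, scores = NULL, track = NULL) {
  stopifnot(nrow(x) == length(names))
  if (is.unsorted(x$start)) stop("BED records must be sorted by start")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(track))
    writeLines(sprintf('track name="%s" description="%s"', track, track), con)
  if (nrow(x) > 0L) {
    cols <- list(x$chrom, format_pos(x$start - 1), format_pos(x$stop), names)
    if (!is.null(scores)) cols <- c(cols, list(format(scores, trim = TRUE)))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param x interval data frame, sorted by start, non-overlapping.
#' @param values finite numeric vector, one per record.
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, values, path, track = NULL) {
  stopifnot(nrow(x) == length(values))
  if (any(!is.finite(values))) stop("bedGraph values must be finite")
  if (is.unsorted(x$start)) stop("bedGraph records must be sorted by start")
  if (nrow(x) > 1L && any(x$stop[-nrow(x)] > x$start[-1L]))
    stop("bedGraph records must not overlap")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(track))
    writeLines(sprintf('track type=bedGraph name="%s"', track), con)
  if (nrow(x) > 0L)
    writeLines(paste(x$chrom, format_pos(x$start - 1), format_pos(x$stop),
                     format(values, trim = TRUE, digits = 15), sep = "\t"), con)
  invisible(path)
}

format_pos <- function(p) format(p, scientific = FALSE, trim = TRUE)

#' Read a 4-column BED file back into printed coordinates
#'
#' Inverse of [write_bed()]: start = BED start + 1 recovers the printed
#' 1-based coordinate exactly.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `stop`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      stop = numeric(), name = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, "", 1L),
             start = as.numeric(vapply(f, `[`, "", 2L)) + 1,
             stop  = as.numeric(vapply(f, `[`, "", 3L)),
             name  = vapply(f, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Read a gene-model table
#'
#' TSV with columns `gene`, `chrom`, `start`, `stop`, `pli` in printed
#' 1-based coordinates. `pli` is the gnomAD probability of loss-of-function
#' intolerance; genes with pli > 0.95 are conventionally flagged as
#' haploinsufficiency-intolerant.
#'
#' @param path TSV file path.
#' @return data.frame with the five columns, validated.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "chrom", "start", "stop", "pli")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene)) stop("gene names must be unique")
  if (any(g$pli < 0 | g$pli > 1)) stop("pli must lie in [0, 1]")
  validate_gi(g)
  g[order(g$start), c("gene", "chrom", "start", "stop", "pli")]
}

#' Bundled hg19 gene models for the 2p15p16.1 region
#'
#' Fifteen genes spanning chr2:56.0-65.5 Mb with approximate RefSeq hg19
#' spans and gnomAD pLI annotations; the ten genes reported as pLI > 0.95 in
#' the region are flagged accordingly.
#'
#' @return gene table data frame (see [read_gene_table()]).
#' @export
gene_table_2p15p16 <- function() {
  read_gene_table(system.file("extdata", "genes_2p15p16_hg19.tsv",
                              package = "sromapper", mustWork = TRUE))
}
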