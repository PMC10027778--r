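#' Genomic intervals in printed-coordinate convention
#'
#' Deletion coordinates in published 2p15p16.1 case tables are 1-based start
#' positions with a Size column equal to `stop - start`; internally intervals
#' are therefore treated as start-inclusive, stop-exclusive. A data frame with
#' columns `chrom`, `start`, `stop` is the interval container used throughout.
#'
#' @param chrom character vector of chromosome names.
#' @param start,stop integer-valued positions; `stop > start` required.
#' @return data.frame with columns `chrom`, `start`, `stop`.
#' @examples
#' gi("chr2", 60689299, 60830491)
#' @export
gi <- function(chrom, start, stop) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  stop  = as.numeric(stop),
                  stringsAsFactors = FALSE)
  validate_gi(x)
  x
}

validate_gi <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "stop") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$stop)))
    stop("interval positions must be finite")
  if (any(x$start <= 0) || any(x$start != round(x$start)) ||
      any(x$stop != round(x$stop)))
    stop("interval positions must be positive integers")
  bad <- which(x$stop <= x$start)
  if (length(bad))
    stop("stop must exceed start (row ", bad[1L], ")")
  invisible(x)
}

#' Interval length under the stop-exclusive convention
#'
#' @param x interval data frame (see [gi()]).
#' @return numeric vector, `stop - start` (reproduces published Size columns).
#' @export
gi_length <- function(x) x$stop - x$start

#' Pairwise interval overlap (>= 1 shared base)
#'
#' Under the stop-exclusive convention two intervals share a base iff
#' `a.start < b.stop && b.start < a.stop`; abutting intervals do not overlap.
#' Intervals on different chromosomes never overlap.
#'
#' @param a single-row interval data frame.
#' @param b interval data frame (recycled comparison against `a`).
#' @return logical vector of length `nrow(b)`.
#' @export
gi_overlaps <- function(a, b) {
  stopifnot(nrow(a) == 1L)
  a$chrom == b$chrom & a$start < b$stop & b$start < a$stop
}

#' Intersection of a set of intervals
#'
#' @param x non-empty interval data frame on a single chromosome.
#' @return single-row interval `[max(start), min(stop)]`, or a zero-row
#'   interval frame when the set has no common base.
#' @export
gi_intersect_all <- function(x) {
  if (nrow(x) == 0L) stop("cannot intersect an empty interval set")
  if (length(unique(x$chrom)) != 1L)
    stop("intersection requires a single chromosome")
  s <- max(x$start); e <- min(x$stop)
  if (e <= s) return(x[0L, c("chrom", "start", "stop")])
  gi(x$chrom[1L], s, e)
}

#' Intervals stabbed by a point
#'
#' A point `p` stabs interval `i` iff `i.start < p <= i.stop`: `p` is read as
#' the identity of the base ending at coordinate `p`, i.e. the last covered
#' base under the stop-exclusive convention. This is the containment rule the
#' SRO construction uses.
#'
#' @param x interval data frame.
#' @param point positive integer position.
#' @return the subset of rows of `x` stabbed by `point`.
#' @export
gi_stabbed_by <- function(x, point) {
  stopifnot(length(point) == 1L, is.finite(point), point > 0)
  x[x$start < point & point <= x$stop, , drop = FALSE]
}

#' @rdname gi_stabbed_by
#' @return for `gi_stabs()`, a logical vector.
#' @export
gi_stabs <- function(x, point) x$start < point & point <= x$stop
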