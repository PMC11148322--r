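# Calibration-free amplitude features: local-SD series, natural visibility
# graph, and graph density. The visibility criterion only compares slopes, so
# density is invariant to recording gain and inter-speaker intensity.

#' Local standard-deviation series
#'
#' The signal is cut into non-overlapping blocks of `L` samples (50 ms at the
#' source rate; the partial final block is dropped) and each block is reduced
#' to its sample standard deviation (denominator `L - 1`).
#'
#' @param ts an [time_series()] or numeric vector
#' @param L block length in samples (1,103 for 22,050-Hz audio, 100 for
#'   2,000-Hz sEMG)
#' @return numeric vector `V` of length `floor(N / L)`
#' @export
local_sd_series <- function(ts, L) {
  x <- if (inherits(ts, "mmb_ts")) ts$samples else as.numeric(ts)
  n <- length(x)
  if (n < 2 * L) stop("series shorter than two blocks (N < 2L)")
  M <- floor(n / L)
  x <- x[seq_len(M * L)]
  m <- matrix(x, nrow = L)
  apply(m, 2, stats::sd)
}

#' Natural visibility graph of a series
#'
#' Vertices are the points of `V`; two vertices `x < y` are connected iff
#' every intermediate vertex `z` satisfies
#' `(V[y] - V[z]) / (y - z) > (V[y] - V[x]) / (y - x)` (strict: collinear
#' points are not visible). Adjacent vertices are always connected.
#'
#' @param V numeric vector (length >= 2)
#' @return object of class `mmb_visgraph`: list with `M` (vertex count),
#'   `edges` (2-column matrix), `m` (edge count)
#' @export
visibility_graph <- function(V) {
  V <- as.numeric(V)
  M <- length(V)
  if (M < 2) stop("need at least 2 vertices")
  from <- integer(0); to <- integer(0)
  for (x in 1:(M - 1)) {
    for (y in (x + 1):M) {
      if (y == x + 1) { from <- c(from, x); to <- c(to, y); next }
      z <- (x + 1):(y - 1)
      lhs <- (V[y] - V[z]) / (y - z)
      rhs <- (V[y] - V[x]) / (y - x)
      if (all(lhs > rhs)) { from <- c(from, x); to <- c(to, y) }
    }
  }
  structure(list(M = M, edges = cbind(from, to), m = length(from)),
            class = "mmb_visgraph")
}

#' @export
print.mmb_visgraph <- function(x, ...) {
  cat(sprintf("<mmb_visgraph> %d vertices, %d edges (density %.3f)\n",
              x$M, x$m, 2 * x$m / (x$M * (x$M - 1))))
  invisible(x)
}

#' Visibility-graph density of a signal
#'
#' `density = 2 m / (M (M - 1))` of the visibility graph built on the
#' local-SD series of the signal. Bounded in `[2/M, 1]` (path graph to
#' complete graph).
#'
#' @param ts an [time_series()] or numeric vector
#' @param L local-SD block length in samples
#' @return scalar density
#' @export
density_feature <- function(ts, L) {
  V <- local_sd_series(ts, L)
  g <- visibility_graph(V)
  2 * g$m / (g$M * (g$M - 1))
}
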