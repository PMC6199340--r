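#' Median-heuristic kernel bandwidth
#'
#' The bandwidth of the Gaussian kernel is the median of the
#' `w (w - 1) / 2` pairwise Euclidean distances between the running
#' autocorrelation vectors.
#'
#' @param P A `running_stats` tibble (or a plain numeric matrix of window
#'   statistics).
#' @return A positive scalar.
#' @export
median_bandwidth <- function(P) {
  h <- cpp_median_bandwidth(stats_matrix(P))
  if (!(h > 0)) {
    stop("degenerate bandwidth: all window statistics coincide", call. = FALSE)
  }
  h
}

#' Gaussian kernel similarity matrix
#'
#' `G[i, j] = exp(-||P_i - P_j||^2 / (2 h^2))`: similarity close to 1 for
#' windows with near-identical autocorrelation vectors, decaying to 0 with
#' distance.
#'
#' @inheritParams median_bandwidth
#' @param h Kernel bandwidth, positive; see [median_bandwidth()].
#' @return A symmetric `w x w` matrix with unit diagonal.
#' @export
kernel_matrix <- function(P, h = median_bandwidth(P)) {
  if (!(h > 0)) stop("`h` must be positive", call. = FALSE)
  cpp_kernel_matrix(stats_matrix(P), h)
}

#' Intra-phase scatter of a block of windows
#'
#' Kernel heterogeneity of windows `a..b`:
#' `L - (1/L) * sum(G[a:b, a:b])` with `L = b - a + 1`. Zero when all
#' vectors in the phase coincide, at most `L - 1`.
#'
#' @param G Kernel matrix.
#' @param a,b First and last window of the phase (inclusive).
#' @return A non-negative scalar.
#' @export
intra_phase_scatter <- function(G, a, b) {
  w <- nrow(G)
  stopifnot(a >= 1, a <= b, b <= w)
  L <- b - a + 1
  L - sum(G[a:b, a:b]) / L
}

#' Variance criterion of a segmentation
#'
#' The per-window average of the intra-phase scatters of the `K + 1` phases
#' delimited by the boundaries.
#'
#' @param G Kernel matrix.
#' @param boundaries Strictly increasing window indices, each the last
#'   window of a phase, all in `[1, w - 1]`. `integer(0)` means no change
#'   point.
#' @return A non-negative scalar.
#' @export
variance_criterion <- function(G, boundaries) {
  w <- nrow(G)
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    stopifnot(all(diff(boundaries) > 0), boundaries[1] >= 1,
              boundaries[length(boundaries)] <= w - 1)
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, w)
  sum(purrr::map2_dbl(starts, ends, ~intra_phase_scatter(G, .x, .y))) / w
}

#' Exact optimal segmentations for K = 0..Kmax change points
#'
#' Minimizes the variance criterion over all admissible boundary placements
#' by dynamic programming over precomputed segment scatters — an exact
#' minimization, not an approximation. Ties are broken toward the
#' lexicographically smallest boundary vector. The minimized criterion is
#' non-increasing in K because the feasible sets are nested.
#'
#' @param G Kernel matrix (see [kernel_matrix()]).
#' @param kmax Largest number of change points to consider (default 10).
#' @param min_phase Minimum number of windows per phase (default 1; a
#'   singleton phase has zero scatter).
#' @return An object of class `kcp_solution`: list with `rmin` (named
#'   numeric, minimized criterion for K = 0..Kmax), `boundaries` (list of
#'   integer vectors, last window of each phase), `w`, `kmax`, `min_phase`.
#' @export
kcp_segment <- function(G, kmax = 10, min_phase = 1) {
  w <- nrow(G)
  if (kmax >= w) stop("`kmax` must be smaller than the number of windows",
                      call. = FALSE)
  res <- cpp_kcp_segment(G, as.integer(kmax), as.integer(min_phase))
  structure(
    list(rmin = setNames(res$rmin, paste0("K", 0:kmax)),
         boundaries = res$boundaries, w = w, kmax = as.integer(kmax),
         min_phase = as.integer(min_phase)),
    class = "kcp_solution"
  )
}

#' @export
print.kcp_solution <- function(x, ...) {
  cat(sprintf("<kcp_solution> w = %d windows, K = 0..%d\n", x$w, x$kmax))
  print(round(x$rmin, 4))
  invisible(x)
}

#' @describeIn kcp_segment Tidy the solution into one row per K with the
#'   minimized criterion and boundary windows.
#' @param x A `kcp_solution`.
#' @param ... Unused.
#' @export
tidy.kcp_solution <- function(x, ...) {
  tibble::tibble(
    k = 0:x$kmax,
    rmin = unname(x$rmin),
    boundaries = lapply(x$boundaries, as.integer)
  )
}

#' Map segmentation boundaries to raw-time change points
#'
#' A boundary `tau` is the last window of a phase; the change point is the
#' first window of the next phase, reported on the raw time axis as the
#' median occasion of that window (`t` column of the running statistics).
#' With equal intervals and window size 25, a boundary at window 90 maps to
#' raw time 103.
#'
#' @param boundaries Integer vector of boundary windows (or a
#'   `kcp_solution` element).
#' @param P The `running_stats` tibble the segmentation was computed on.
#' @return Numeric vector of raw-time change points.
#' @export
map_to_raw_time <- function(boundaries, P) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) == 0) return(numeric(0))
  w <- nrow(P)
  stopifnot(all(boundaries >= 1), all(boundaries <= w - 1))
  P$t[boundaries + 1L]
}
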