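# Choosing the number of change points: the variance-drop permutation test
# (step 1) and the penalty-coefficient grid search (step 2).

# Internal: full segmentation pipeline on a raw matrix.
kcp_fit_matrix <- function(X, window, kmax, min_phase) {
  P <- cpp_running_autocor(X, as.integer(window))
  if (anyNA(P)) stop("constant window in the series", call. = FALSE)
  h <- cpp_median_bandwidth(P)
  if (!(h > 0)) stop("degenerate bandwidth", call. = FALSE)
  G <- cpp_kernel_matrix(P, h)
  seg <- cpp_kcp_segment(G, as.integer(kmax), as.integer(min_phase))
  list(P = P, h = h, rmin = seg$rmin, boundaries = seg$boundaries)
}

#' Variance-drop permutation test for at least one change point
#'
#' The observed statistic is the maximal improvement
#' `rmin[K - 1] - rmin[K]` over `K = 1..kmax`, computed on the running
#' autocorrelations of the series. Its null distribution is obtained by
#' reshuffling the raw time points uniformly at random — destroying the
#' serial dependence and hence any autocorrelation structure — and
#' recomputing the whole pipeline (running autocorrelations, bandwidth,
#' kernel, segmentation) on each permuted series. The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`, which
#' never reports exactly zero; the plain proportion is returned alongside.
#'
#' @param data Series data frame.
#' @param window Sliding-window size (default 25).
#' @param kmax Largest number of change points considered (default 10).
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param min_phase Minimum windows per phase.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `kcp_drop_test`: list with `statistic`,
#'   `null_stats`, `p_value` (add-one), `p_value_plain`, `n_perm`, `alpha`,
#'   `reject`.
#' @export
variance_drop_test <- function(data, window = 25, kmax = 10, n_perm = 1000,
                               alpha = 0.05, min_phase = 1, seed = NULL) {
  stopifnot(n_perm >= 0, kmax >= 1)
  X <- series_matrix(data)
  fit <- kcp_fit_matrix(X, window, kmax, min_phase)
  statistic <- max(fit$rmin[-length(fit$rmin)] - fit$rmin[-1])
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- NA_real_
    for (try in 1:100) {
      s <- cpp_max_variance_drop(X[sample.int(n), , drop = FALSE],
                                 as.integer(window), as.integer(kmax),
                                 as.integer(min_phase))
      if (!is.na(s)) break
    }
    if (is.na(s)) stop("permutation produced a degenerate series 100 times",
                       call. = FALSE)
    null_stats[b] <- s
  }
  exceed <- sum(null_stats >= statistic)
  p <- (1 + exceed) / (1 + n_perm)
  structure(
    list(statistic = statistic, null_stats = null_stats, p_value = p,
         p_value_plain = if (n_perm > 0) exceed / n_perm else NA_real_,
         n_perm = n_perm, alpha = alpha, reject = p <= alpha),
    class = "kcp_drop_test"
  )
}

#' @export
print.kcp_drop_test <- function(x, ...) {
  cat(sprintf(paste0("Variance-drop permutation test: statistic = %.4f, ",
                     "p = %.4g (%d permutations)\n"),
              x$statistic, x$p_value, x$n_perm))
  cat(if (x$reject) "At least one change point declared.\n"
      else "No change point declared.\n")
  invisible(x)
}

#' Scale constant of the segmentation penalty
#'
#' The empirical covariance matrix of the first and of the last 5% of the
#' running-statistic rows (`ceiling(0.05 w)` each) is computed; each matrix
#' is reduced to its largest diagonal entry (maximum variance), and the
#' larger of the two scalars is returned.
#'
#' @inheritParams median_bandwidth
#' @return A non-negative scalar.
#' @export
estimate_vmax <- function(P) {
  M <- stats_matrix(P)
  w <- nrow(M)
  m <- ceiling(0.05 * w)
  if (m < 2) stop("5% slice has fewer than 2 rows; series too short",
                  call. = FALSE)
  max(max(diag(cov(M[seq_len(m), , drop = FALSE]))),
      max(diag(cov(M[seq.int(w - m + 1, w), , drop = FALSE]))))
}

#' Penalty term of the penalized change-point count
#'
#' `pen_K = C * v_max * (K + 1) / w * (1 + log(w / (K + 1)))`: linear in
#' the penalty coefficient `C` and in the scale constant `v_max`,
#' increasing in `K`.
#'
#' @param C Penalty coefficient, positive.
#' @param K Number of change points, `0 <= K <= w - 1`.
#' @param v_max Scale constant, see [estimate_vmax()].
#' @param w Number of windows.
#' @return The penalty value (vectorized over `K`).
#' @export
penalty_term <- function(C, K, v_max, w) {
  stopifnot(C > 0, w >= 1, all(K >= 0), all(K <= w - 1))
  C * v_max * (K + 1) / w * (1 + log(w / (K + 1)))
}

#' Penalty-coefficient grid search for the number of change points
#'
#' Sweeps `C = c_start, c_start + c_step, ...`; at each `C` the penalized
#' count `K(C) = argmin_K rmin[K] + pen_K(C)` is recorded (ties toward
#' smaller K). Because the penalty is increasing in K and linear in C,
#' `K(C)` is non-increasing. The sweep stops at the first `C` with
#' `K(C) = 0`; the selected K is the most frequent value among the
#' non-zero `K(C)` encountered (ties toward smaller K) — the terminal
#' `K = 0` run is excluded, since it would otherwise always win.
#'
#' @param solution A `kcp_solution` (or its `rmin` vector for K = 0..Kmax).
#' @param v_max Scale constant, see [estimate_vmax()].
#' @param w Number of windows.
#' @param c_start First penalty coefficient (default 1).
#' @param c_step Grid increment (default 0.05).
#' @return An object of class `kcp_grid`: list with `trace` (tibble of `c`
#'   and `k`), `selected_k`.
#' @export
grid_search_k <- function(solution, v_max, w, c_start = 1, c_step = 0.05) {
  rmin <- if (inherits(solution, "kcp_solution")) solution$rmin else solution
  if (!(v_max > 0)) stop("`v_max` must be positive for the grid search",
                         call. = FALSE)
  kvals <- seq_along(rmin) - 1L
  cs <- numeric(0)
  ks <- integer(0)
  C <- c_start
  repeat {
    k <- kvals[which.min(rmin + penalty_term(C, kvals, v_max, w))]
    if (k == 0L) break
    cs <- c(cs, C)
    ks <- c(ks, k)
    C <- C + c_step
    if (length(ks) > 2e5) {
      warning("grid search did not reach K = 0; stopping early")
      break
    }
  }
  if (length(ks) == 0) {
    warning("penalized selection already prefers K = 0 at the starting C")
    selected <- 0L
  } else {
    counts <- table(ks)
    best <- max(counts)
    selected <- min(as.integer(names(counts)[counts == best]))
  }
  structure(
    list(trace = tibble::tibble(c = c(cs, C), k = c(ks, 0L)),
         selected_k = selected),
    class = "kcp_grid"
  )
}

#' @export
print.kcp_grid <- function(x, ...) {
  cat(sprintf("<kcp_grid> %d grid points, selected K = %d\n",
              nrow(x$trace), x$selected_k))
  invisible(x)
}

# Per-phase lag-1 autocorrelations of the raw series split at raw-time
# change points.
phase_autocorrelations <- function(data, change_points) {
  X <- series_matrix(data)
  t_raw <- series_time(data)
  phase <- partition_from_changepoints(change_points, n = nrow(X), at = t_raw)
  purrr::map_dfr(sort(unique(phase)), function(p) {
    rows <- which(phase == p)
    xs <- X[rows, , drop = FALSE]
    tibble::tibble(
      phase = p,
      start = t_raw[rows[1]],
      end = t_raw[rows[length(rows)]],
      variable = colnames(X),
      autocorrelation = apply(xs, 2, function(x) {
        if (length(x) < 3 || sd(head(x, -1)) == 0 || sd(tail(x, -1)) == 0) {
          return(NA_real_)
        }
        cor(head(x, -1), tail(x, -1))
      })
    )
  })
}

#' KCP-AR: kernel change point detection on running autocorrelations
#'
#' The full two-step detector. Step 1 runs the variance-drop permutation
#' test; if it does not reject at `alpha`, no change point is declared
#' (`selected_k = 0`). Step 2, on rejection, runs the penalty grid search
#' to pick K, maps the optimal boundaries back to raw time (median occasion
#' of the first window of each new phase) and, as an auxiliary analysis,
#' computes the per-phase lag-1 autocorrelation of every variable on the
#' raw series split at the detected change points.
#'
#' @inheritParams variance_drop_test
#' @param c_start,c_step Grid-search start and increment, see
#'   [grid_search_k()].
#' @return An object of class `kcp_ar`: list with `p_value`,
#'   `p_value_plain`, `statistic`, `selected_k`, `change_points` (raw
#'   time), `boundaries` (window units), `rmin`, `grid` (trace tibble or
#'   NULL), `test`, `running` (the `running_stats` tibble),
#'   `phase_autocorrelations` tibble, `config`.
#' @examples
#' \donttest{
#' sim <- simulate_phase_var1(toy_design(), seed = 7)
#' fit <- kcp_ar(sim, n_perm = 200, seed = 7)
#' fit$change_points
#' }
#' @export
kcp_ar <- function(data, window = 25, kmax = 10, n_perm = 1000, alpha = 0.05,
                   c_start = 1, c_step = 0.05, min_phase = 1, seed = NULL) {
  data <- tibble::as_tibble(data)
  P <- running_autocorrelations(data, window)
  G <- kernel_matrix(P)
  solution <- kcp_segment(G, kmax = kmax, min_phase = min_phase)
  test <- variance_drop_test(data, window = window, kmax = kmax,
                             n_perm = n_perm, alpha = alpha,
                             min_phase = min_phase, seed = seed)
  grid <- NULL
  selected_k <- 0L
  change_points <- numeric(0)
  if (test$reject) {
    v_max <- estimate_vmax(P)
    grid <- grid_search_k(solution, v_max, w = nrow(P),
                          c_start = c_start, c_step = c_step)
    selected_k <- grid$selected_k
    if (selected_k > 0) {
      change_points <- map_to_raw_time(solution$boundaries[[selected_k + 1L]],
                                       P)
    }
  }
  structure(
    list(p_value = test$p_value, p_value_plain = test$p_value_plain,
         statistic = test$statistic, selected_k = selected_k,
         change_points = change_points,
         boundaries = if (selected_k > 0) {
           as.integer(solution$boundaries[[selected_k + 1L]])
         } else integer(0),
         rmin = solution$rmin, solution = solution,
         grid = if (!is.null(grid)) grid$trace else NULL,
         test = test, running = P,
         phase_autocorrelations = phase_autocorrelations(data, change_points),
         config = list(window = window, kmax = kmax, n_perm = n_perm,
                       alpha = alpha, c_start = c_start, c_step = c_step,
                       min_phase = min_phase, seed = seed)),
    class = "kcp_ar"
  )
}

#' @export
print.kcp_ar <- function(x, ...) {
  cat("KCP-AR change point analysis\n")
  cat(sprintf("  windows: %d (size %d)   permutations: %d\n",
              nrow(x$running), x$config$window, x$config$n_perm))
  cat(sprintf("  variance-drop test: statistic = %.4f, p = %.4g\n",
              x$statistic, x$p_value))
  if (x$selected_k == 0) {
    cat("  no change point declared (K = 0)\n")
  } else {
    cat(sprintf("  selected K = %d; change points at t = %s\n", x$selected_k,
                paste(format(x$change_points), collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn kcp_ar One row per phase and variable with the phase's
#'   lag-1 autocorrelation.
#' @param x A `kcp_ar` object.
#' @param ... Unused.
#' @export
tidy.kcp_ar <- function(x, ...) {
  x$phase_autocorrelations
}

#' @describeIn kcp_ar One-row model summary (p-value, selected K, statistic,
#'   number of windows).
#' @export
glance.kcp_ar <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, p_value_plain = x$p_value_plain,
    statistic = x$statistic, selected_k = x$selected_k,
    n_change_points = length(x$change_points),
    w = nrow(x$running), window = x$config$window,
    n_perm = x$config$n_perm, alpha = x$config$alpha
  )
}
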