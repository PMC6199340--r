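#' Phase-structured VAR(1) generative design
#'
#' Describes a piecewise-stationary diagonal VAR(1) process: within phase
#' `p`, each variable `v` follows `x[i, v] = phi[p, v] * x[i - 1, v] + e[i, v]`
#' with innovations `e[i, ] ~ MVN(0, Sigma_r)` where `Sigma_r` has unit
#' variances and all off-diagonal entries equal to `r`. Change points are
#' abrupt: the first occasion of a new phase already uses the new
#' autoregression, and the chain is never re-initialized at a boundary, so
#' the marginal variance is allowed to grow with `phi` (for a constant
#' phase, it approaches `1 / (1 - phi^2)`).
#'
#' @param phi Matrix of autoregression coefficients, one row per phase and
#'   one column per variable, all entries strictly inside (-1, 1). A vector
#'   is taken as a single-variable design (one entry per phase).
#' @param phase_lengths Positive integer vector, time points per phase.
#' @param r Innovation cross-correlation shared by all variable pairs, in
#'   (-1, 1) and above `-1/(V - 1)` so the covariance is positive definite.
#' @param label Optional free-text label.
#' @return An object of class `phase_design`.
#' @examples
#' phase_design(rbind(0, 0.5, 0), c(100, 100, 100), r = 0)
#' @export
phase_design <- function(phi, phase_lengths, r = 0, label = NULL) {
  if (is.vector(phi)) phi <- matrix(phi, ncol = 1)
  phi <- as.matrix(phi)
  V <- ncol(phi)
  if (nrow(phi) != length(phase_lengths)) {
    stop("`phi` must have one row per phase", call. = FALSE)
  }
  if (any(phase_lengths < 1) || any(phase_lengths != round(phase_lengths))) {
    stop("all phase lengths must be positive integers", call. = FALSE)
  }
  if (any(abs(phi) >= 1)) {
    stop("all autoregression coefficients must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  if (abs(r) >= 1) {
    stop("cross-correlation `r` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (V > 1 && r <= -1 / (V - 1)) {
    stop(sprintf(paste0("innovation covariance is not positive definite: ",
                        "with V = %d, `r` must exceed %.4f"), V, -1 / (V - 1)),
         call. = FALSE)
  }
  structure(
    list(V = V, phase_lengths = as.integer(phase_lengths), phi = phi, r = r,
         label = label %||% "design"),
    class = "phase_design"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.phase_design <- function(x, ...) {
  cat(sprintf("<phase_design> %s: V = %d, phases = %s, r = %.2f\n",
              x$label, x$V, paste(x$phase_lengths, collapse = "/"), x$r))
  cat("phi:\n")
  print(x$phi)
  invisible(x)
}

# Attach study descriptors (used by run_study/summarize_study).
design_descriptor <- function(design, ...) {
  design$descriptor <- list(...)
  design
}

#' The three-phase toy design
#'
#' Three variables, three phases of 100 time points, per-variable
#' autocorrelation 0 then 0.5 then 0, uncorrelated innovations. The true
#' change points sit at occasions 101 and 201.
#'
#' @return A `phase_design`.
#' @export
toy_design <- function() {
  d <- phase_design(
    phi = rbind(rep(0, 3), rep(0.5, 3), rep(0, 3)),
    phase_lengths = c(100, 100, 100),
    r = 0, label = "toy"
  )
  design_descriptor(d, r = 0, V = 3L, S = 3L, delta_phi = 0.5, n_cp = 2L,
                    phase_length = 100L)
}

#' Full factorial simulation-study grid
#'
#' Crosses innovation correlation `r` in {0, 0.60}, system size `V` in
#' {1, 2, 3, 5, 7}, number of changing variables `S` from 1 (uncorrelated)
#' or 2 (correlated) up to `V`, and autocorrelation shift `delta_phi` in
#' {0.20, 0.40, 0.60}. With one change point, two phases are generated and
#' the changing variables move from 0 to `delta_phi`; with two change
#' points, three phases with the shift reverting to 0. Non-changing (noise)
#' variables keep autocorrelation 0 throughout. The univariate cell exists
#' only for zero `r` (cross-correlation is undefined for V = 1).
#'
#' @param n_change_points 1 or 2.
#' @param phase_length Time points per phase (the study uses 100 and 50).
#' @return A list of `phase_design` objects.
#' @export
study_grid <- function(n_change_points = 1, phase_length = 100) {
  stopifnot(n_change_points %in% c(1, 2))
  designs <- list()
  for (r in c(0, 0.60)) {
    for (V in c(1L, 2L, 3L, 5L, 7L)) {
      if (r > 0 && V == 1L) next
      s_min <- if (r == 0) 1L else 2L
      if (s_min > V) next
      for (S in seq.int(s_min, V)) {
        for (dphi in c(0.20, 0.40, 0.60)) {
          row_change <- c(rep(dphi, S), rep(0, V - S))
          row_zero <- rep(0, V)
          phi <- if (n_change_points == 1) {
            rbind(row_zero, row_change)
          } else {
            rbind(row_zero, row_change, row_zero)
          }
          lab <- sprintf("cp%d_r%.2f_V%d_S%d_d%.2f_len%d",
                         n_change_points, r, V, S, dphi, phase_length)
          d <- phase_design(phi, rep(phase_length, n_change_points + 1),
                            r = r, label = lab)
          d <- design_descriptor(d, r = r, V = V, S = S, delta_phi = dphi,
                                 n_cp = as.integer(n_change_points),
                                 phase_length = as.integer(phase_length))
          designs[[length(designs) + 1L]] <- d
        }
      }
    }
  }
  designs
}

#' Single-phase null design
#'
#' Constant autocorrelation throughout: the generative setting of the
#' type-I-error study, where any declared change point is a false alarm.
#'
#' @param V Number of variables.
#' @param phi_level Constant autocorrelation for all variables (the study
#'   uses 0, 0.20, 0.40 and 0.60).
#' @param n Series length (the number of time points is not dictated by the
#'   design; 200 matches the one-change-point total).
#' @param r Innovation cross-correlation.
#' @return A `phase_design` with a single phase.
#' @export
null_design <- function(V, phi_level, n = 200, r = 0) {
  d <- phase_design(matrix(phi_level, nrow = 1, ncol = V), n, r = r,
                    label = sprintf("null_V%d_phi%.2f_n%d", V, phi_level, n))
  design_descriptor(d, r = r, V = as.integer(V), S = 0L,
                    delta_phi = 0, n_cp = 0L, phase_length = as.integer(n))
}
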