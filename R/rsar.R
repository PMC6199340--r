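# Regime-switching AR(1) by maximum likelihood. The observation equation is
# X_i = alpha + diag(phi^r) X_{i-1} + eps_i, eps_i ~ MVN(0, Sigma), with the
# regime r following a first-order hidden Markov chain. By default only phi
# switches across regimes, intercepts are fixed at zero and Sigma is shared
# — the constraint set used to isolate autodependency changes.

# Normalize user parameters to the shapes the C++ filter expects.
rsar_params <- function(phi, sigma, trans, alpha, init, V) {
  if (is.vector(phi)) phi <- matrix(phi, nrow = 1)
  phi <- as.matrix(phi)
  R <- nrow(phi)
  stopifnot(ncol(phi) == V)
  if (is.null(alpha)) alpha <- matrix(0, R, V)
  if (is.vector(alpha)) alpha <- matrix(alpha, R, V, byrow = TRUE)
  if (is.matrix(sigma)) {
    sigma <- array(sigma, dim = c(V, V, R))
  }
  stopifnot(all(dim(sigma) == c(V, V, R)))
  if (is.null(trans)) trans <- diag(R)
  trans <- as.matrix(trans)
  stopifnot(nrow(trans) == R, ncol(trans) == R,
            all(abs(rowSums(trans) - 1) < 1e-8), all(trans >= 0))
  if (is.null(init)) init <- rep(1 / R, R)
  stopifnot(length(init) == R, abs(sum(init) - 1) < 1e-8)
  list(phi = phi, alpha = alpha, sigma = sigma, trans = trans,
       init = as.numeric(init), R = R)
}

#' Exact log-likelihood of a regime-switching AR(1) model
#'
#' The filtered log-likelihood of `X_2..X_n` given `X_1`, computed by the
#' forward (Hamilton) recursion. Because the AR(1) state is fully observed,
#' the Kalman prediction and update steps of the usual filtering scheme are
#' exact identities and the collapsing step is lossless, so this recursion
#' is the exact marginalization over all regime sequences.
#'
#' @param data Series data frame.
#' @param phi `R x V` matrix of autoregression coefficients (rows per
#'   regime; a vector for a single regime).
#' @param sigma `V x V` innovation covariance (shared), or a `V x V x R`
#'   array for regime-specific covariances.
#' @param trans `R x R` transition matrix (rows sum to 1). Defaults to the
#'   identity for a single regime.
#' @param alpha Intercepts: vector of length V (shared) or `R x V` matrix;
#'   default zero.
#' @param init Initial regime distribution; default uniform.
#' @return The log-likelihood (scalar).
#' @export
rsar_loglik <- function(data, phi, sigma, trans = NULL, alpha = NULL,
                        init = NULL) {
  X <- series_matrix(data)
  p <- rsar_params(phi, sigma, trans, alpha, init, ncol(X))
  out <- cpp_rsar_filter(X, p$alpha, p$phi, p$sigma, p$trans, p$init)
  if (!out$ok) stop("likelihood evaluation failed (non-PD covariance?)",
                    call. = FALSE)
  out$loglik
}

# Closed-form single-regime ML fit: per-variable least-squares AR(1) slope
# (through the origin when the intercept is fixed at zero) and the ML
# residual covariance over the n - 1 modeled transitions.
rsar_ols <- function(X, intercept = FALSE) {
  n <- nrow(X)
  Xp <- X[-n, , drop = FALSE]
  Xc <- X[-1, , drop = FALSE]
  V <- ncol(X)
  phi <- numeric(V)
  alpha <- numeric(V)
  for (v in seq_len(V)) {
    if (intercept) {
      cf <- stats::lm.fit(cbind(1, Xp[, v]), Xc[, v])$coefficients
      alpha[v] <- cf[1]
      phi[v] <- cf[2]
    } else {
      phi[v] <- sum(Xp[, v] * Xc[, v]) / sum(Xp[, v]^2)
    }
  }
  E <- Xc - matrix(alpha, n - 1, V, byrow = TRUE) -
    Xp * matrix(phi, n - 1, V, byrow = TRUE)
  sigma <- crossprod(E) / (n - 1)
  list(phi = phi, alpha = alpha, sigma = sigma)
}

# Free-parameter count under the constraint flags (initial regime
# distribution is fixed uniform and carries no parameters).
rsar_n_params <- function(R, V, fix_alpha_zero, switch_alpha, switch_sigma) {
  p_phi <- R * V
  p_alpha <- if (fix_alpha_zero) 0 else if (switch_alpha) R * V else V
  p_sigma <- V * (V + 1) / 2 * (if (switch_sigma) R else 1)
  p_trans <- R * (R - 1)
  p_phi + p_alpha + p_sigma + p_trans
}

#' Fit a regime-switching AR(1) model by maximum likelihood
#'
#' Maximizes the exact filtered likelihood with an
#' expectation-conditional-maximization algorithm: forward-backward
#' smoothing in the E-step and closed-form conditional updates for the
#' autoregression coefficients (per-regime generalized least squares), the
#' intercepts, the innovation covariance and the transition rows. Each
#' conditional update cannot decrease the likelihood, so the iteration
#' ascends monotonically. `n_starts` random initializations (the first
#' anchored at the single-regime least-squares fit with regimes spread
#' around it, transition matrices drawn persistent) guard against local
#' optima; every start is run for a short burn-in and only the most
#' promising are iterated to convergence (the usual short-run strategy for
#' EM multistarts). Regimes are relabeled in increasing order of
#' `mean(phi^r)` for reproducible reporting.
#'
#' @param data Series data frame.
#' @param regimes Number of regimes R (>= 1).
#' @param fix_alpha_zero Fix all intercepts at zero (default TRUE, the
#'   constraint used throughout the simulations).
#' @param switch_alpha If intercepts are free, estimate them per regime
#'   rather than shared (default FALSE).
#' @param switch_sigma Estimate a regime-specific innovation covariance
#'   rather than a shared one (default FALSE).
#' @param n_starts Number of multistart initializations (default 10).
#' @param maxit,tol ECM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param posterior Use smoothed (full-sample, default) or filtered regime
#'   probabilities for the reported regime path.
#' @param seed Optional integer seed for the multistart draws.
#' @return An object of class `rsar`: list with `phi` (`R x V`), `alpha`,
#'   `sigma` (`V x V x R` array; slices equal when shared), `trans`,
#'   `init`, `loglik`, `n_params`, `aic`, `bic`, `n_eff`, `posterior`
#'   (tibble `t`, `.regime`, one probability column per regime),
#'   `assignments`, convergence info and the constraint flags.
#' @examples
#' \donttest{
#' sim <- simulate_phase_var1(toy_design(), seed = 7)
#' fit <- fit_rsar(sim, regimes = 2, seed = 7)
#' round(fit$phi, 2)
#' }
#' @export
fit_rsar <- function(data, regimes = 2, fix_alpha_zero = TRUE,
                     switch_alpha = FALSE, switch_sigma = FALSE,
                     n_starts = 10, maxit = 500, tol = 1e-6,
                     posterior = c("smoothed", "filtered"), seed = NULL) {
  posterior <- match.arg(posterior)
  X <- series_matrix(data)
  n <- nrow(X)
  V <- ncol(X)
  R <- as.integer(regimes)
  stopifnot(R >= 1)
  n_params <- rsar_n_params(R, V, fix_alpha_zero, switch_alpha, switch_sigma)
  if (n - 1 < 2 * n_params) {
    warning(sprintf("only %d transitions for %d free parameters", n - 1,
                    n_params))
  }
  alpha_mode <- if (fix_alpha_zero) 0L else if (switch_alpha) 2L else 1L
  sigma_mode <- if (switch_sigma) 1L else 0L
  init <- rep(1 / R, R)
  ols <- rsar_ols(X, intercept = !fix_alpha_zero)

  if (R == 1L) {
    best <- list(
      phi = matrix(ols$phi, 1, V), alpha = matrix(ols$alpha, 1, V),
      sigma = array(ols$sigma, dim = c(V, V, 1)), trans = matrix(1, 1, 1),
      loglik = NA_real_, iterations = 0L, converged = TRUE
    )
    fb <- cpp_rsar_filter(X, best$alpha, best$phi, best$sigma, best$trans,
                          init)
    if (!fb$ok) stop("single-regime fit is degenerate", call. = FALSE)
    best$loglik <- fb$loglik
  } else {
    if (!is.null(seed)) set.seed(seed)
    short <- list()
    for (s in seq_len(n_starts)) {
      if (s == 1) {
        spread <- seq(-0.25, 0.25, length.out = R)
        phi0 <- outer(spread, rep(1, V)) +
          matrix(ols$phi, R, V, byrow = TRUE)
      } else {
        phi0 <- matrix(ols$phi, R, V, byrow = TRUE) +
          matrix(rnorm(R * V, sd = 0.3), R, V)
      }
      phi0 <- pmin(pmax(phi0, -0.95), 0.95)
      alpha0 <- matrix(ols$alpha, R, V, byrow = TRUE)
      sigma0 <- array(ols$sigma, dim = c(V, V, R))
      trans0 <- matrix(0.1 / (R - 1) + runif(R * R, 0, 0.02), R, R)
      diag(trans0) <- diag(trans0) + 0.8
      trans0 <- trans0 / rowSums(trans0)
      fit <- cpp_rsar_em(X, alpha0, phi0, sigma0, trans0, init,
                         alpha_mode, sigma_mode, min(40L, maxit), tol)
      if (!fit$ok || !is.finite(fit$loglik)) next
      short[[length(short) + 1L]] <- fit
    }
    if (length(short) == 0) {
      stop("all multistart fits failed (degenerate likelihood)", call. = FALSE)
    }
    # iterate the most promising short runs to full convergence
    lls <- vapply(short, function(f) f$loglik, numeric(1))
    best <- NULL
    for (s in utils::head(order(lls, decreasing = TRUE), 3L)) {
      f0 <- short[[s]]
      fit <- cpp_rsar_em(X, f0$alpha, f0$phi, f0$sigma, f0$trans, init,
                         alpha_mode, sigma_mode, as.integer(maxit), tol)
      if (!fit$ok || !is.finite(fit$loglik)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) {
      stop("all multistart fits failed (degenerate likelihood)", call. = FALSE)
    }
    # relabel regimes by increasing mean autoregression
    ord <- order(rowMeans(best$phi))
    best$phi <- best$phi[ord, , drop = FALSE]
    best$alpha <- best$alpha[ord, , drop = FALSE]
    best$sigma <- best$sigma[, , ord, drop = FALSE]
    best$trans <- best$trans[ord, ord, drop = FALSE]
  }

  fb <- cpp_rsar_filter(X, best$alpha, best$phi, best$sigma, best$trans, init)
  probs <- if (posterior == "smoothed") fb$smoothed else fb$filtered
  assignments <- apply(probs, 1, which.max)  # ties fall to the lower regime
  n_eff <- n - 1
  loglik <- fb$loglik
  vars <- series_vars(data)
  colnames(best$phi) <- vars
  post <- tibble::as_tibble(
    setNames(as.data.frame(probs), paste0("p_regime", seq_len(R)))
  )
  post <- dplyr::bind_cols(
    tibble::tibble(t = series_time(data), .regime = as.integer(assignments)),
    post
  )
  structure(
    list(phi = best$phi, alpha = best$alpha, sigma = best$sigma,
         trans = best$trans, init = init, loglik = loglik,
         n_params = n_params, n_eff = n_eff,
         aic = -2 * loglik + 2 * n_params,
         bic = -2 * loglik + n_params * log(n_eff),
         R = R, V = V, variables = vars,
         posterior = post, assignments = as.integer(assignments),
         posterior_mode = posterior,
         converged = isTRUE(best$converged), iterations = best$iterations,
         flags = list(fix_alpha_zero = fix_alpha_zero,
                      switch_alpha = switch_alpha,
                      switch_sigma = switch_sigma),
         config = list(n_starts = n_starts, maxit = maxit, tol = tol,
                       seed = seed)),
    class = "rsar"
  )
}

#' @export
print.rsar <- function(x, ...) {
  cat(sprintf("Regime-switching AR(1): R = %d regimes, V = %d variables\n",
              x$R, x$V))
  cat(sprintf("  log-likelihood %.3f | AIC %.2f | BIC %.2f (p = %d)\n",
              x$loglik, x$aic, x$bic, x$n_params))
  cat("  phi (rows = regimes):\n")
  print(round(x$phi, 3))
  if (x$R > 1) {
    cat("  transition matrix:\n")
    print(round(x$trans, 3))
  }
  invisible(x)
}

#' Information criteria of a fitted regime-switching model
#'
#' `AIC = -2 logL + 2 p` and `BIC = -2 logL + p log(n_eff)`, where `p`
#' counts only the free parameter blocks (per-regime autoregressions,
#' intercepts unless fixed, the innovation covariance, and the transition
#' rows) and `n_eff` is the number of modeled transitions, `n - 1`.
#'
#' @param model A fitted `rsar` object.
#' @param n_eff Override for the effective sample size (defaults to the
#'   model's transition count).
#' @return A one-row tibble with `aic`, `bic`, `loglik`, `n_params`, `n_eff`.
#' @export
information_criteria <- function(model, n_eff = NULL) {
  stopifnot(inherits(model, "rsar"))
  n_eff <- n_eff %||% model$n_eff
  tibble::tibble(
    aic = -2 * model$loglik + 2 * model$n_params,
    bic = -2 * model$loglik + model$n_params * log(n_eff),
    loglik = model$loglik, n_params = model$n_params, n_eff = n_eff
  )
}

#' Posterior regime probabilities and assignments
#'
#' Recomputes the forward pass (and, for smoothed probabilities, the
#' backward pass) of the fitted model on a series and assigns every
#' occasion to its highest-probability regime, ties falling to the lower
#' regime index. The first occasion carries no observation of its own; its
#' probabilities reflect only the chain prior and smoothing.
#'
#' @param model A fitted `rsar` object.
#' @param data Series data frame (defaults to reusing the stored posterior
#'   if omitted).
#' @param type `"smoothed"` (default) or `"filtered"`.
#' @return A tibble with `t`, `.regime` and one probability column per
#'   regime; rows sum to 1.
#' @export
posterior_regimes <- function(model, data = NULL,
                              type = c("smoothed", "filtered")) {
  stopifnot(inherits(model, "rsar"))
  type <- match.arg(type)
  if (is.null(data) && type == model$posterior_mode) return(model$posterior)
  if (is.null(data)) stop("supply `data` to recompute posteriors",
                          call. = FALSE)
  X <- series_matrix(data)
  fb <- cpp_rsar_filter(X, model$alpha, model$phi, model$sigma, model$trans,
                        model$init)
  if (!fb$ok) stop("filter failed on the supplied data", call. = FALSE)
  probs <- if (type == "smoothed") fb$smoothed else fb$filtered
  out <- tibble::as_tibble(
    setNames(as.data.frame(probs), paste0("p_regime", seq_len(model$R)))
  )
  dplyr::bind_cols(
    tibble::tibble(t = series_time(data),
                   .regime = as.integer(apply(probs, 1, which.max))),
    out
  )
}

#' Choose the number of regimes by AIC and BIC
#'
#' Fits the model for every R in `regimes` and returns the AIC-minimizing
#' and the BIC-minimizing fits (they may differ). A change in
#' autodependency is declared when the chosen number of regimes exceeds
#' one.
#'
#' @inheritParams fit_rsar
#' @param regimes Integer vector of regime counts to fit (default 1:3).
#' @param ... Passed on to [fit_rsar()].
#' @return An object of class `rsar_selection`: list with `table` (one row
#'   per R: loglik, n_params, aic, bic), `models`, `best_aic`, `best_bic`,
#'   `r_aic`, `r_bic`.
#' @export
select_regimes <- function(data, regimes = 1:3, seed = NULL, ...) {
  stopifnot(length(regimes) >= 1)
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(regimes))
  } else {
    as.list(seed + seq_along(regimes) - 1L)
  }
  models <- purrr::map2(regimes, seeds,
                        function(R, s) fit_rsar(data, regimes = R, seed = s,
                                                ...))
  tab <- purrr::map_dfr(models, function(m) {
    tibble::tibble(regimes = m$R, loglik = m$loglik, n_params = m$n_params,
                   aic = m$aic, bic = m$bic, converged = m$converged)
  })
  i_aic <- which.min(tab$aic)
  i_bic <- which.min(tab$bic)
  structure(
    list(table = tab, models = models,
         best_aic = models[[i_aic]], best_bic = models[[i_bic]],
         r_aic = tab$regimes[i_aic], r_bic = tab$regimes[i_bic]),
    class = "rsar_selection"
  )
}

#' @export
print.rsar_selection <- function(x, ...) {
  cat("Regime number selection\n")
  print(as.data.frame(dplyr::mutate(x$table, dplyr::across(
    c("loglik", "aic", "bic"), ~round(.x, 2)))))
  cat(sprintf("AIC chooses R = %d; BIC chooses R = %d\n", x$r_aic, x$r_bic))
  invisible(x)
}

#' @describeIn fit_rsar One row per regime and variable with the estimated
#'   autoregression (and intercept when free).
#' @param x An `rsar` object.
#' @param ... Unused.
#' @export
tidy.rsar <- function(x, ...) {
  out <- tibble::tibble(
    regime = rep(seq_len(x$R), each = x$V),
    variable = rep(x$variables, times = x$R),
    phi = as.vector(t(x$phi))
  )
  if (!x$flags$fix_alpha_zero) out$alpha <- as.vector(t(x$alpha))
  out
}

#' @describeIn fit_rsar One-row fit summary (log-likelihood, AIC, BIC,
#'   parameter count, convergence).
#' @export
glance.rsar <- function(x, ...) {
  tibble::tibble(
    regimes = x$R, loglik = x$loglik, aic = x$aic, bic = x$bic,
    n_params = x$n_params, n_eff = x$n_eff, converged = x$converged
  )
}

#' @describeIn select_regimes The per-R criterion table.
#' @param x An `rsar_selection` object.
#' @param ... Unused.
#' @export
tidy.rsar_selection <- function(x, ...) {
  x$table
}
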