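test_that("filtered log-likelihood equals regime-sequence enumeration", {
  set.seed(41)
  for (i in 1:20) {
    R <- sample(2:3, 1)
    V <- sample(1:2, 1)
    n <- sample(5:8, 1)
    p <- random_rsar_params(R, V)
    X <- matrix(rnorm(n * V), n, V)
    data <- tibble::as_tibble(setNames(as.data.frame(X), paste0("X", seq_len(V))))
    ll <- rsar_loglik(data, phi = p$phi, sigma = p$sigma, trans = p$trans,
                      init = p$init)
    oracle <- oracle_rsar_loglik(X, p$phi, sigma_list_from(p$sigma, R),
                                 p$trans, p$init)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("single-regime likelihood is the Gaussian AR(1) closed form", {
  set.seed(42)
  X <- series_matrix(simulate_phase_var1(phase_design(0.5, 60)))
  phi <- 0.4
  s2 <- 1.3
  ll <- rsar_loglik(tibble::tibble(x = X[, 1]), phi = phi,
                    sigma = matrix(s2, 1, 1))
  resid <- X[-1, 1] - phi * X[-nrow(X), 1]
  expect_equal(ll, sum(dnorm(resid, 0, sqrt(s2), log = TRUE)),
               tolerance = 1e-10)
})

test_that("an absorbing chain reduces to the single-regime likelihood", {
  set.seed(43)
  X <- matrix(rnorm(40), 20, 2)
  data <- tibble::tibble(X1 = X[, 1], X2 = X[, 2])
  p <- random_rsar_params(2, 2)
  ll_abs <- rsar_loglik(data, phi = p$phi, sigma = p$sigma,
                        trans = diag(2), init = c(0, 1))
  ll_one <- rsar_loglik(data, phi = p$phi[2, , drop = FALSE],
                        sigma = p$sigma)
  expect_equal(ll_abs, ll_one, tolerance = 1e-10)
})

test_that("smoothed posteriors equal enumeration marginals", {
  set.seed(44)
  for (i in 1:10) {
    R <- 2
    V <- 1
    n <- 7
    p <- random_rsar_params(R, V)
    X <- matrix(rnorm(n * V), n, V)
    fb <- autoshift:::cpp_rsar_filter(
      X, matrix(0, R, V), p$phi, array(p$sigma, c(V, V, R)), p$trans, p$init)
    oracle <- oracle_rsar_posterior(X, p$phi, sigma_list_from(p$sigma, R),
                                    p$trans, p$init)
    expect_equal(fb$smoothed, oracle, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(rowSums(fb$smoothed), rep(1, n), tolerance = 1e-10)
    expect_equal(rowSums(fb$filtered), rep(1, n), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to relabeling the regimes", {
  set.seed(45)
  p <- random_rsar_params(3, 2)
  X <- matrix(rnorm(60), 30, 2)
  data <- tibble::tibble(X1 = X[, 1], X2 = X[, 2])
  perm <- c(3, 1, 2)
  ll1 <- rsar_loglik(data, phi = p$phi, sigma = p$sigma, trans = p$trans,
                     init = p$init)
  ll2 <- rsar_loglik(data, phi = p$phi[perm, ], sigma = p$sigma,
                     trans = p$trans[perm, perm], init = p$init[perm])
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("single-regime fit recovers the least-squares closed form", {
  set.seed(46)
  sim <- simulate_phase_var1(phase_design(matrix(c(0.3, 0.6), 1), 150))
  X <- series_matrix(sim)
  fit <- fit_rsar(sim, regimes = 1)
  ls_phi <- vapply(1:2, function(v) {
    sum(X[-1, v] * X[-150, v]) / sum(X[-150, v]^2)
  }, numeric(1))
  expect_equal(as.numeric(fit$phi), ls_phi, tolerance = 1e-6)
  resid <- X[-1, ] - X[-150, ] %*% diag(as.numeric(fit$phi))
  expect_equal(fit$sigma[, , 1], crossprod(resid) / 149, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("parameter counts follow the free blocks", {
  sim <- simulate_phase_var1(toy_design(), seed = 47)
  f2 <- fit_rsar(sim, regimes = 2, n_starts = 2, seed = 1)
  expect_equal(f2$n_params, 6 + 6 + 2)  # phi (2x3) + Sigma + transitions
  f1 <- fit_rsar(sim, regimes = 1)
  expect_equal(f1$n_params, 3 + 6)      # phi + Sigma, alpha fixed at zero
  expect_equal(f1$aic - f1$bic, f1$n_params * (2 - log(f1$n_eff)))
  ic <- information_criteria(f2)
  expect_equal(ic$aic, -2 * f2$loglik + 2 * 14)
  expect_equal(ic$bic, -2 * f2$loglik + 14 * log(299))
  # freeing alpha adds V (shared) or R*V (switching) parameters
  fa <- fit_rsar(sim, regimes = 2, fix_alpha_zero = FALSE, n_starts = 2,
                 seed = 1)
  expect_equal(fa$n_params, 14 + 3)
  fs <- fit_rsar(sim, regimes = 2, fix_alpha_zero = FALSE,
                 switch_alpha = TRUE, switch_sigma = TRUE, n_starts = 2,
                 seed = 1)
  expect_equal(fs$n_params, 6 + 6 + 2 * 6 + 2)
})

test_that("more regimes cannot lose likelihood (up to multistart noise)", {
  sim <- simulate_phase_var1(null_design(2, 0.3, 150), seed = 48)
  f1 <- fit_rsar(sim, regimes = 1)
  f2 <- fit_rsar(sim, regimes = 2, seed = 2)
  expect_gte(f2$loglik, f1$loglik - 1e-4)
})

test_that("ECM iterations never decrease the likelihood", {
  set.seed(49)
  sim <- simulate_phase_var1(toy_design())
  X <- series_matrix(sim)
  p <- random_rsar_params(2, 3)
  lls <- numeric(0)
  params <- list(alpha = matrix(0, 2, 3), phi = p$phi,
                 sigma = array(p$sigma, c(3, 3, 2)), trans = p$trans)
  for (step in 1:8) {
    fit <- autoshift:::cpp_rsar_em(X, params$alpha, params$phi, params$sigma,
                                   params$trans, rep(0.5, 2), 0L, 0L, 1L,
                                   1e-12)
    lls <- c(lls, fit$loglik)
    params <- list(alpha = fit$alpha, phi = fit$phi, sigma = fit$sigma,
                   trans = fit$trans)
  }
  expect_true(all(diff(lls) > -1e-6))
})

test_that("two clearly separated regimes are recovered", {
  sim <- simulate_phase_var1(
    phase_design(rbind(rep(0, 3), rep(0.6, 3)), c(150, 150)), seed = 50)
  fit <- fit_rsar(sim, regimes = 2, seed = 50)
  # regimes are sorted by mean phi, so row 1 is the low-dependency regime
  expect_true(all(abs(fit$phi[1, ] - 0) < 0.15))
  expect_true(all(abs(fit$phi[2, ] - 0.6) < 0.15))
  truth <- rep(1:2, each = 150)
  expect_gt(rand_index(fit$assignments, truth), 0.9)
  expect_equal(rowSums(fit$trans), c(1, 1), tolerance = 1e-10)
  post <- posterior_regimes(fit, sim)
  expect_equal(rowSums(as.matrix(post[paste0("p_regime", 1:2)])),
               rep(1, 300), tolerance = 1e-8)
  # tidiers
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_equal(names(glance(fit))[1:4],
               c("regimes", "loglik", "aic", "bic"))
})

test_that("select_regimes returns both criteria and nested feasibility", {
  sim <- simulate_phase_var1(toy_design(), seed = 51)
  sel <- select_regimes(sim, regimes = 1:3, seed = 51)
  expect_equal(sel$table$regimes, 1:3)
  expect_true(all(diff(sel$table$loglik) > -1e-3))
  expect_s3_class(sel$best_aic, "rsar")
  expect_s3_class(sel$best_bic, "rsar")
  expect_equal(sel$r_aic, sel$table$regimes[which.min(sel$table$aic)])
  sel1 <- select_regimes(sim, regimes = 1)
  expect_equal(sel1$r_aic, 1)
  expect_equal(sel1$r_bic, 1)
})
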