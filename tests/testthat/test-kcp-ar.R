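test_that("variance-drop statistic matches the segmentation path", {
  sim <- simulate_phase_var1(toy_design(), seed = 2)
  P <- running_autocorrelations(sim)
  sol <- kcp_segment(kernel_matrix(P), kmax = 10)
  tst <- variance_drop_test(sim, n_perm = 5, seed = 1)
  expect_equal(tst$statistic,
               max(sol$rmin[-length(sol$rmin)] - sol$rmin[-1]))
})

test_that("permutation p-value follows the add-one estimator", {
  sim <- simulate_phase_var1(null_design(2, 0, 80), seed = 3)
  tst <- variance_drop_test(sim, n_perm = 19, seed = 4)
  expect_equal(tst$p_value,
               (1 + sum(tst$null_stats >= tst$statistic)) / 20)
  expect_equal(tst$p_value_plain, mean(tst$null_stats >= tst$statistic))
  # zero permutations can never reject
  t0 <- variance_drop_test(sim, n_perm = 0)
  expect_equal(t0$p_value, 1)
  expect_false(t0$reject)
})

test_that("the test is deterministic under a fixed seed", {
  sim <- simulate_phase_var1(toy_design(), seed = 5)
  a <- variance_drop_test(sim, n_perm = 30, seed = 11)
  b <- variance_drop_test(sim, n_perm = 30, seed = 11)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(a$p_value, b$p_value)
})

test_that("v_max takes the larger maximum variance of the two 5% slices", {
  # w = 40 so each slice holds the first/last 2 rows; variances are then
  # (x1 - x2)^2 / 2 per column, fixed by construction
  M <- matrix(0, 40, 2)
  M[1, ] <- c(sqrt(0.2), sqrt(0.6))    # head variances 0.1, 0.3
  M[39, ] <- c(sqrt(0.4), sqrt(0.5))   # tail variances 0.2, 0.25
  expect_equal(estimate_vmax(M), 0.3)
  # scaling the statistics by c scales v_max by c^2
  expect_equal(estimate_vmax(3 * M), 9 * 0.3)
  expect_error(estimate_vmax(M[1:20, ]), "fewer than 2")
  expect_equal(estimate_vmax(matrix(1, 40, 2)), 0)
})

test_that("penalty term matches the closed formula", {
  expect_equal(penalty_term(1, 0, 1, exp(1)), 2 / exp(1))
  expect_equal(penalty_term(3, 2, 0.5, 50),
               3 * penalty_term(1, 2, 0.5, 50))
  expect_equal(penalty_term(2, 1, 4, 50), 4 * penalty_term(2, 1, 1, 50))
  # K + 1 = w collapses the bracket to 1
  expect_equal(penalty_term(2, 9, 0.7, 10), 2 * 0.7)
})

test_that("grid search finds a dominant drop and is monotone in C", {
  # rmin with one large drop at K = 1 then a flat tail
  rmin <- c(1, 0.2, 0.19, 0.185)
  g <- grid_search_k(rmin, v_max = 0.5, w = 100)
  expect_equal(g$selected_k, 1)
  expect_true(all(diff(g$trace$k) <= 0))
  counts <- table(g$trace$k[g$trace$k > 0])
  expect_equal(g$selected_k, as.integer(names(which.max(counts))))
})

test_that("grid search K(C) is non-increasing on random criterion curves", {
  set.seed(12)
  for (i in 1:20) {
    rmin <- rev(cumsum(c(0, runif(6))))  # non-increasing in K
    g <- grid_search_k(rmin, v_max = runif(1, 0.1, 2), w = 80,
                       c_step = 0.2)
    expect_true(all(diff(g$trace$k) <= 0))
  }
})

test_that("grid search warns when K = 0 wins immediately", {
  rmin <- c(0.01, 0.0099, 0.0098)
  expect_warning(g <- grid_search_k(rmin, v_max = 10, w = 50), "K = 0")
  expect_equal(g$selected_k, 0)
})

test_that("kcp_ar output is internally consistent", {
  sim <- simulate_phase_var1(toy_design(), seed = 1)
  fit <- kcp_ar(sim, n_perm = 100, seed = 1)
  expect_s3_class(fit, "kcp_ar")
  if (fit$selected_k == 0) {
    expect_length(fit$change_points, 0)
  } else {
    expect_length(fit$change_points, fit$selected_k)
    expect_true(all(diff(fit$change_points) > 0))
    # change points are the window medians following the boundaries
    expect_equal(fit$change_points,
                 map_to_raw_time(fit$boundaries, fit$running))
  }
  expect_true(all(diff(fit$rmin) <= 1e-12))
  # phase autocorrelation table covers every phase x variable
  expect_equal(nrow(tidy(fit)), (fit$selected_k + 1) * 3)
  expect_equal(nrow(glance(fit)), 1)
  # determinism under the seed
  fit2 <- kcp_ar(sim, n_perm = 100, seed = 1)
  expect_equal(fit$p_value, fit2$p_value)
  expect_equal(fit$change_points, fit2$change_points)
})

test_that("a non-significant gate reports no change points", {
  sim <- simulate_phase_var1(null_design(3, 0.2, 120), seed = 99)
  fit <- kcp_ar(sim, n_perm = 39, alpha = 0.001, seed = 2)
  expect_equal(fit$selected_k, 0)
  expect_length(fit$change_points, 0)
  expect_null(fit$grid)
  expect_equal(unique(tidy(fit)$phase), 1)
})

test_that("phase autocorrelations on toy data track the generating phi", {
  set.seed(77)
  vals <- replicate(10, {
    sim <- simulate_phase_var1(toy_design())
    pa <- autoshift:::phase_autocorrelations(sim, c(101, 201))
    tapply(pa$autocorrelation, pa$phase, mean)
  })
  m <- rowMeans(vals)
  expect_lt(abs(m[1] - 0), 0.1)
  expect_lt(abs(m[2] - 0.5), 0.1)
  expect_lt(abs(m[3] - 0), 0.1)
})
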