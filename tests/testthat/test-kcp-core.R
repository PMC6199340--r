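test_that("median bandwidth matches enumerated pairwise distances", {
  # two rows at distance 3-4-5
  expect_equal(median_bandwidth(rbind(c(0, 0), c(3, 4))), 5)
  # rows 0, 1, 2 in one dimension: distances {1, 1, 2}, median 1
  expect_equal(median_bandwidth(matrix(c(0, 1, 2), 3, 1)), 1)
  # even pair count uses the mean of the two middle distances
  M <- matrix(c(0, 1, 3, 7), 4, 1)
  d <- as.numeric(dist(M))
  expect_equal(median_bandwidth(M), median(d))
  # invariance under joint rotation
  set.seed(2)
  P <- matrix(rnorm(20), 10, 2)
  th <- 0.7
  Q <- P %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(median_bandwidth(P), median_bandwidth(Q), tolerance = 1e-12)
  expect_error(median_bandwidth(matrix(1, 5, 2)), "degenerate")
})

test_that("Gaussian kernel has the forced analytic values", {
  P <- rbind(c(0, 0), c(1, 0), c(0, 0))
  G <- kernel_matrix(P, h = 1)
  expect_equal(diag(G), rep(1, 3))
  expect_equal(G[1, 3], 1)             # identical rows
  expect_equal(G[1, 2], exp(-1 / 2))   # distance equal to the bandwidth
  # similarity decays monotonically with distance
  Pd <- matrix(c(0, 1, 2, 5, 20), 5, 1)
  Gd <- kernel_matrix(Pd, h = 1)
  expect_true(all(diff(Gd[1, -1]) < 0))
  expect_error(kernel_matrix(P, h = 0), "positive")
})

test_that("intra-phase scatter matches its expanded form", {
  set.seed(3)
  G <- random_kernel(8)
  expect_equal(intra_phase_scatter(G, 4, 4), 0)              # singleton
  Gid <- kernel_matrix(matrix(1, 5, 1) %*% c(1, 2), h = 1)
  expect_equal(intra_phase_scatter(Gid, 1, 5), 0)            # identical rows
  # two windows with cross-similarity g: scatter = 1 - g
  g <- G[3, 4]
  expect_equal(intra_phase_scatter(G, 3, 4), 1 - g)
})

test_that("variance criterion is the mean of per-phase scatters", {
  set.seed(4)
  for (i in 1:10) {
    G <- random_kernel(sample(6:12, 1))
    w <- nrow(G)
    K <- sample(0:3, 1)
    tau <- if (K > 0) sort(sample(seq_len(w - 1), K)) else integer(0)
    expect_equal(variance_criterion(G, tau), oracle_criterion(G, tau))
  }
  # all singleton phases give zero
  G <- random_kernel(6)
  expect_equal(variance_criterion(G, 1:5), 0)
})

test_that("dynamic program equals exhaustive enumeration on small inputs", {
  set.seed(5)
  for (i in 1:25) {
    w <- sample(6:12, 1)
    G <- random_kernel(w)
    kmax <- sample(1:3, 1)
    sol <- kcp_segment(G, kmax = kmax)
    for (K in 0:kmax) {
      oracle <- oracle_segmentation(G, K)
      expect_equal(unname(sol$rmin[K + 1]), oracle$criterion,
                   tolerance = 1e-10)
      expect_equal(as.integer(sol$boundaries[[K + 1]]),
                   as.integer(oracle$boundaries %||% integer(0)))
    }
  }
})

test_that("minimized criterion is non-increasing in K", {
  set.seed(6)
  for (i in 1:10) {
    G <- random_kernel(sample(15:40, 1))
    sol <- kcp_segment(G, kmax = 5)
    expect_true(all(diff(sol$rmin) <= 1e-12))
  }
})

test_that("exact ties resolve to the lexicographically smallest boundaries", {
  # constant off-diagonal similarity: every segmentation with the same K has
  # the same criterion, so the DP must return the smallest boundary vector
  G <- matrix(0.5, 8, 8)
  diag(G) <- 1
  sol <- kcp_segment(G, kmax = 3)
  expect_equal(as.integer(sol$boundaries[[2]]), 1L)
  expect_equal(as.integer(sol$boundaries[[3]]), 1:2)
  expect_equal(as.integer(sol$boundaries[[4]]), 1:3)
})

test_that("returned segmentation beats random user segmentations", {
  set.seed(7)
  G <- random_kernel(30)
  sol <- kcp_segment(G, kmax = 4)
  for (i in 1:20) {
    K <- sample(1:4, 1)
    tau <- sort(sample(seq_len(29), K))
    expect_lte(unname(sol$rmin[K + 1]),
               variance_criterion(G, tau) + 1e-12)
  }
})

test_that("permuting the variables of P leaves the segmentation unchanged", {
  sim <- simulate_phase_var1(toy_design(), seed = 9)
  P <- running_autocorrelations(sim)
  Pm <- P[c("window", "t", "X3", "X1", "X2")]
  class(Pm) <- class(P)
  s1 <- kcp_segment(kernel_matrix(P), kmax = 4)
  s2 <- kcp_segment(kernel_matrix(Pm), kmax = 4)
  expect_equal(s1$rmin, s2$rmin)
  expect_equal(s1$boundaries, s2$boundaries)
})

test_that("minimum phase length constrains admissible boundaries", {
  set.seed(10)
  G <- random_kernel(10)
  sol <- kcp_segment(G, kmax = 2, min_phase = 3)
  for (K in 1:2) {
    tau <- sol$boundaries[[K + 1]]
    expect_true(all(diff(c(0, tau, 10)) >= 3))
    oracle <- oracle_segmentation(G, K, min_phase = 3)
    expect_equal(unname(sol$rmin[K + 1]), oracle$criterion, tolerance = 1e-10)
  }
  expect_error(kcp_segment(G, kmax = 9, min_phase = 3), "admissible")
})

test_that("boundaries map to the median occasion of the next window", {
  sim <- simulate_phase_var1(toy_design(), seed = 1)
  P <- running_autocorrelations(sim, window = 25)
  # boundary tau = 90: new phase starts at window 91 covering 91..115
  expect_equal(map_to_raw_time(90, P), 103)
  expect_equal(map_to_raw_time(c(90, 190), P), c(103, 203))
  expect_equal(map_to_raw_time(integer(0), P), numeric(0))
  # with unequal raw times the mapping is a lookup, not arithmetic
  P2 <- P
  P2$t <- P$t * 2
  expect_equal(map_to_raw_time(90, P2), 206)
})
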