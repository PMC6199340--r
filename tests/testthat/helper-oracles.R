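# Independent oracles for the heavy machinery: brute-force enumeration and
# closed forms that never touch the code paths they check.

`%||%` <- function(x, y) if (is.null(x)) y else x

sigma_list_from <- function(sigma, R) replicate(R, sigma, simplify = FALSE)

# All admissible boundary vectors (last window of each phase) for K change
# points over w windows with a minimum phase length.
all_boundary_vectors <- function(w, K, min_phase = 1) {
  if (K == 0) return(list(integer(0)))
  cand <- utils::combn(seq_len(w - 1), K, simplify = FALSE)
  Filter(function(tau) {
    lens <- diff(c(0L, tau, w))
    all(lens >= min_phase)
  }, cand)
}

# Criterion of one segmentation straight from its definition (double sums).
oracle_criterion <- function(G, tau) {
  w <- nrow(G)
  starts <- c(1L, tau + 1L)
  ends <- c(tau, w)
  total <- 0
  for (m in seq_along(starts)) {
    idx <- starts[m]:ends[m]
    L <- length(idx)
    total <- total + (L - sum(G[idx, idx]) / L)
  }
  total / w
}

# Exhaustive minimization: minimal criterion and the lexicographically
# smallest minimizer.
oracle_segmentation <- function(G, K, min_phase = 1) {
  best <- Inf
  best_tau <- NULL
  for (tau in all_boundary_vectors(nrow(G), K, min_phase)) {
    val <- oracle_criterion(G, tau)
    if (val < best) {
      best <- val
      best_tau <- tau
    }
  }
  list(criterion = best, boundaries = best_tau)
}

oracle_logdmvnorm <- function(x, mean, sigma) {
  U <- chol(sigma)
  z <- backsolve(U, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

# Log weight of every regime sequence r_1..r_n: log prior of the path plus
# the Gaussian log density of each observed transition. Per-occasion
# densities are tabulated first; the enumeration itself stays exhaustive.
oracle_rsar_terms <- function(X, phi, sigma_list, trans, init, alpha) {
  n <- nrow(X)
  R <- nrow(phi)
  if (is.null(alpha)) alpha <- matrix(0, R, ncol(X))
  logd <- matrix(0, n, R)  # density of X_i under regime t (rows 2..n)
  for (i in 2:n) {
    for (t in seq_len(R)) {
      logd[i, t] <- oracle_logdmvnorm(
        X[i, ], alpha[t, ] + phi[t, ] * X[i - 1, ], sigma_list[[t]])
    }
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(R)), n)))
  terms <- apply(seqs, 1, function(rs) {
    log(init[rs[1]]) + sum(log(trans[cbind(rs[-n], rs[-1])])) +
      sum(logd[cbind(2:n, rs[-1])])
  })
  list(seqs = seqs, terms = terms)
}

# Brute-force regime-switching AR(1) log-likelihood of X[2..n] | X[1]:
# log-sum over all R^n regime sequences of prior x Gaussian likelihood.
oracle_rsar_loglik <- function(X, phi, sigma_list, trans, init, alpha = NULL) {
  terms <- oracle_rsar_terms(X, phi, sigma_list, trans, init, alpha)$terms
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# Smoothed marginal P[r_i = t | X] by the same enumeration.
oracle_rsar_posterior <- function(X, phi, sigma_list, trans, init,
                                  alpha = NULL) {
  en <- oracle_rsar_terms(X, phi, sigma_list, trans, init, alpha)
  wts <- exp(en$terms - max(en$terms))
  wts <- wts / sum(wts)
  n <- nrow(X)
  R <- nrow(phi)
  post <- matrix(0, n, R)
  for (i in seq_len(n)) {
    for (t in seq_len(R)) post[i, t] <- sum(wts[en$seqs[, i] == t])
  }
  post
}

# Rand index by explicit enumeration of all unordered pairs.
oracle_rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / total
}

# Random correlation-like running-stats matrix and its kernel, for small
# segmentation instances.
random_kernel <- function(w, V = 2) {
  P <- matrix(runif(w * V, -1, 1), w, V)
  h <- autoshift::median_bandwidth(P)
  autoshift::kernel_matrix(P, h)
}

# Random valid regime-switching parameters.
random_rsar_params <- function(R, V) {
  phi <- matrix(runif(R * V, -0.8, 0.8), R, V)
  A <- matrix(rnorm(V * V), V)
  sigma <- crossprod(A) / V + diag(V)
  trans <- matrix(runif(R * R, 0.2, 1), R, R)
  trans <- trans / rowSums(trans)
  init <- rep(1 / R, R)
  list(phi = phi, sigma = sigma, trans = trans, init = init)
}

toy_series <- function(seed) {
  autoshift::simulate_phase_var1(autoshift::toy_design(), seed = seed)
}
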