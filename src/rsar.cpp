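// Regime-switching AR(1): exact filtered likelihood (Hamilton recursion),
// forward-backward smoothing, and ECM maximum-likelihood estimation.
//
// The AR(1) state is fully observed, so the regime-conditional density of
// X_i given X_{i-1} depends only on the current regime: the model is a plain
// hidden Markov model whose emission at time i is the one-step-ahead
// prediction error d_i = X_i - alpha_r - diag(phi_r) X_{i-1} under a
// Gaussian innovation law. The forward pass below is therefore the exact
// marginal likelihood (no collapsing approximation is needed).
//
// Emission densities and M-step moments are computed with matrix operations
// over all n - 1 transitions at once; only the O(n R^2) chain recursions
// remain explicit loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Log Gaussian emission matrix ((n-1) x R). alpha, phi are R x V; sigma is
// V x V x R (slices equal when shared). Returns false on a non-PD sigma.
static bool emission_logdens(const arma::mat& X1, const arma::mat& X2,
                             const arma::mat& alpha, const arma::mat& phi,
                             const arma::cube& sigma, arma::mat& logb) {
  const int V = X1.n_cols, R = phi.n_rows;
  const double cst = -0.5 * V * std::log(2.0 * arma::datum::pi);
  logb.set_size(X1.n_rows, R);
  for (int r = 0; r < R; ++r) {
    arma::mat W;
    if (!arma::inv_sympd(W, sigma.slice(r))) return false;
    double ldet, sign;
    arma::log_det(ldet, sign, sigma.slice(r));
    if (sign <= 0) return false;
    arma::mat D = X2 - (X1.each_row() % phi.row(r));
    D.each_row() -= alpha.row(r);
    logb.col(r) = cst - 0.5 * ldet - 0.5 * arma::sum((D * W) % D, 1);
  }
  return true;
}

struct FB {
  double loglik;
  arma::mat filtered, smoothed, xi_sum;
  bool ok;
};

static FB forward_backward(const arma::mat& logb, const arma::mat& trans,
                           const arma::vec& init) {
  const int m = logb.n_rows;  // transitions
  const int R = trans.n_rows;
  const int n = m + 1;
  FB out;
  out.ok = true;
  arma::mat a(n, R), bscaled(m, R);
  arma::vec cs(m), mx(m);
  a.row(0) = init.t();
  double loglik = 0.0;
  for (int i = 1; i < n; ++i) {
    mx[i - 1] = logb.row(i - 1).max();
    bscaled.row(i - 1) = arma::exp(logb.row(i - 1) - mx[i - 1]);
    arma::rowvec u = (a.row(i - 1) * trans) % bscaled.row(i - 1);
    const double c = arma::accu(u);
    if (!(c > 0) || !std::isfinite(c)) { out.ok = false; return out; }
    cs[i - 1] = c;
    a.row(i) = u / c;
    loglik += std::log(c) + mx[i - 1];
  }
  arma::mat beta(n, R, arma::fill::ones), gamma(n, R);
  arma::mat xi_sum(R, R, arma::fill::zeros);
  gamma.row(n - 1) = a.row(n - 1);
  for (int i = n - 1; i >= 1; --i) {
    arma::rowvec bb = bscaled.row(i - 1) % beta.row(i);
    xi_sum += (a.row(i - 1).t() * bb) % trans / cs[i - 1];
    beta.row(i - 1) = (trans * bb.t()).t() / cs[i - 1];
    gamma.row(i - 1) = a.row(i - 1) % beta.row(i - 1);
    gamma.row(i - 1) /= arma::accu(gamma.row(i - 1));
  }
  out.loglik = loglik;
  out.filtered = a;
  out.smoothed = gamma;
  out.xi_sum = xi_sum;
  return out;
}

// Exact filtered log-likelihood of X_2..X_n | X_1 plus filtered/smoothed
// regime probabilities (n x R; the first row carries the regime
// distribution of occasion 1, which emits no observation) and summed
// transition responsibilities.
// [[Rcpp::export]]
List cpp_rsar_filter(const arma::mat& X, const arma::mat& alpha,
                     const arma::mat& phi, const arma::cube& sigma,
                     const arma::mat& trans, const arma::vec& init) {
  const int n = X.n_rows;
  const arma::mat X1 = X.rows(0, n - 2), X2 = X.rows(1, n - 1);
  arma::mat logb;
  if (!emission_logdens(X1, X2, alpha, phi, sigma, logb))
    return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
  FB fb = forward_backward(logb, trans, init);
  if (!fb.ok)
    return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
  return List::create(_["ok"] = true, _["loglik"] = fb.loglik,
                      _["filtered"] = fb.filtered,
                      _["smoothed"] = fb.smoothed,
                      _["xi_sum"] = fb.xi_sum);
}

// ECM fit from one starting point. Conditional M-steps (all closed-form):
// per-regime GLS update of phi, then alpha, then the innovation
// covariance, then the transition rows; each conditional update cannot
// decrease the expected complete-data log-likelihood, so the observed
// log-likelihood ascends monotonically (up to round-off).
//
// alpha_mode: 0 fixed at zero, 1 shared across regimes, 2 regime-specific.
// sigma_mode: 0 shared, 1 regime-specific.
// [[Rcpp::export]]
List cpp_rsar_em(const arma::mat& X, arma::mat alpha, arma::mat phi,
                 arma::cube sigma, arma::mat trans, const arma::vec& init,
                 const int alpha_mode, const int sigma_mode,
                 const int maxit, const double tol) {
  const int n = X.n_rows, V = X.n_cols, R = phi.n_rows;
  const arma::mat X1 = X.rows(0, n - 2), X2 = X.rows(1, n - 1);
  double loglik = R_NegInf;
  bool converged = false;
  int iter = 0;
  arma::mat logb;

  for (iter = 1; iter <= maxit; ++iter) {
    if (!emission_logdens(X1, X2, alpha, phi, sigma, logb))
      return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
    FB fb = forward_backward(logb, trans, init);
    if (!fb.ok)
      return List::create(_["ok"] = false, _["loglik"] = R_NegInf);

    if (std::isfinite(loglik) &&
        std::fabs(fb.loglik - loglik) < tol * (1.0 + std::fabs(fb.loglik))) {
      loglik = fb.loglik;
      converged = true;
      break;
    }
    loglik = fb.loglik;

    // emission weights: smoothed probabilities of occasions 2..n
    arma::mat g = fb.smoothed.rows(1, n - 1);  // (n-1) x R
    arma::rowvec wsum = arma::sum(g, 0);

    std::vector<arma::mat> W(R);
    for (int r = 0; r < R; ++r) {
      if (!arma::inv_sympd(W[r], sigma.slice(r)))
        return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
    }

    // --- phi: per regime, (W .* Cxx) phi = colsum of g .* (X1 .* ((X2 - alpha) W))
    for (int r = 0; r < R; ++r) {
      if (!(wsum[r] > 0)) continue;
      const arma::vec gr = g.col(r);
      arma::mat Cxx = X1.t() * (X1.each_col() % gr);
      arma::mat Yw = (X2.each_row() - alpha.row(r)) * W[r];
      arma::vec b = (X1 % Yw).t() * gr;
      arma::mat A = W[r] % Cxx;
      arma::vec sol;
      if (arma::solve(sol, A, b, arma::solve_opts::no_approx))
        phi.row(r) = sol.t();
    }

    // --- alpha
    if (alpha_mode == 1) {
      arma::mat Aa(V, V, arma::fill::zeros);
      arma::vec ba(V, arma::fill::zeros);
      for (int r = 0; r < R; ++r) {
        arma::mat D = X2 - (X1.each_row() % phi.row(r));
        Aa += wsum[r] * W[r];
        ba += W[r] * (D.t() * g.col(r));
      }
      arma::vec asol;
      if (arma::solve(asol, Aa, ba, arma::solve_opts::no_approx))
        alpha.each_row() = asol.t();
    } else if (alpha_mode == 2) {
      for (int r = 0; r < R; ++r) {
        if (!(wsum[r] > 0)) continue;
        arma::mat D = X2 - (X1.each_row() % phi.row(r));
        alpha.row(r) = (D.t() * g.col(r)).t() / wsum[r];
      }
    }

    // --- sigma
    if (sigma_mode == 0) {
      arma::mat S(V, V, arma::fill::zeros);
      for (int r = 0; r < R; ++r) {
        arma::mat E = X2 - (X1.each_row() % phi.row(r));
        E.each_row() -= alpha.row(r);
        S += E.t() * (E.each_col() % g.col(r));
      }
      sigma.each_slice() = S / (n - 1);
    } else {
      for (int r = 0; r < R; ++r) {
        if (!(wsum[r] > 0)) continue;
        arma::mat E = X2 - (X1.each_row() % phi.row(r));
        E.each_row() -= alpha.row(r);
        sigma.slice(r) = E.t() * (E.each_col() % g.col(r)) / wsum[r];
      }
    }

    // --- transition rows from expected counts
    for (int s = 0; s < R; ++s) {
      const double rs = arma::accu(fb.xi_sum.row(s));
      if (rs > 0) trans.row(s) = fb.xi_sum.row(s) / rs;
    }
  }

  // final likelihood under the last parameter update
  if (emission_logdens(X1, X2, alpha, phi, sigma, logb)) {
    FB fb = forward_backward(logb, trans, init);
    if (fb.ok) loglik = fb.loglik;
  }

  return List::create(_["ok"] = true, _["loglik"] = loglik,
                      _["alpha"] = alpha, _["phi"] = phi,
                      _["sigma"] = sigma, _["trans"] = trans,
                      _["iterations"] = iter, _["converged"] = converged);
}
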