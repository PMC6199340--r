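// Kernel change point machinery on running autocorrelations.
//
// The permutation test recomputes the whole pipeline (running
// autocorrelations -> bandwidth -> kernel -> segmentation) for every
// reshuffled series, so these steps are compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Lag-1 Pearson autocorrelation within each sliding window of `window`
// consecutive rows (window - 1 lagged pairs). Returns a (n - window + 1) x V
// matrix; entries are NaN where either lagged segment is constant.
// [[Rcpp::export]]
arma::mat cpp_running_autocor(const arma::mat& X, const int window) {
  const int n = X.n_rows, V = X.n_cols;
  const int w = n - window + 1;
  const int m = window - 1;  // lagged pairs per window
  arma::mat P(w, V);
  for (int v = 0; v < V; ++v) {
    const arma::vec x = X.col(v);
    for (int s = 0; s < w; ++s) {
      // pairs (x[s + k], x[s + k + 1]), k = 0..m-1; centered two-pass sums
      // so large offsets do not lose precision
      double sa = 0, sb = 0;
      for (int k = 0; k < m; ++k) {
        sa += x[s + k];
        sb += x[s + k + 1];
      }
      const double ma = sa / m, mb = sb / m;
      double va = 0, vb = 0, cab = 0;
      for (int k = 0; k < m; ++k) {
        const double a = x[s + k] - ma, b = x[s + k + 1] - mb;
        va += a * a; vb += b * b; cab += a * b;
      }
      if (va <= 0.0 || vb <= 0.0) {
        P(s, v) = arma::datum::nan;
      } else {
        P(s, v) = cab / std::sqrt(va * vb);
      }
    }
  }
  return P;
}

// Median of the w(w-1)/2 pairwise Euclidean distances between rows of P,
// using the same even-count convention as stats::median.
// [[Rcpp::export]]
double cpp_median_bandwidth(const arma::mat& P) {
  const int w = P.n_rows;
  if (w < 2) stop("need at least two rows to compute a bandwidth");
  std::vector<double> d;
  d.reserve((size_t)w * (w - 1) / 2);
  for (int i = 0; i < w - 1; ++i)
    for (int j = i + 1; j < w; ++j)
      d.push_back(std::sqrt(arma::accu(arma::square(P.row(i) - P.row(j)))));
  const size_t M = d.size();
  const size_t k = M / 2;
  std::nth_element(d.begin(), d.begin() + k, d.end());
  double hi = d[k];
  if (M % 2 == 1) return hi;
  std::nth_element(d.begin(), d.begin() + k - 1, d.begin() + k);
  return 0.5 * (d[k - 1] + hi);
}

// Gaussian kernel similarity matrix G_ij = exp(-||P_i - P_j||^2 / (2 h^2)).
// [[Rcpp::export]]
arma::mat cpp_kernel_matrix(const arma::mat& P, const double h) {
  if (!(h > 0)) stop("bandwidth must be positive");
  const int w = P.n_rows;
  arma::mat G(w, w, arma::fill::ones);
  const double c = 1.0 / (2.0 * h * h);
  for (int i = 0; i < w - 1; ++i)
    for (int j = i + 1; j < w; ++j) {
      const double d2 = arma::accu(arma::square(P.row(i) - P.row(j)));
      G(i, j) = G(j, i) = std::exp(-d2 * c);
    }
  return G;
}

// Segment cost ("intra-phase scatter") of windows [a, b] (0-based, inclusive)
// from the 2-D prefix sum of G: cost = L - S(a,b)/L, L = b - a + 1.
static inline double seg_cost(const arma::mat& Gp, const int a, const int b) {
  const double L = b - a + 1;
  const double S = Gp(b + 1, b + 1) - Gp(a, b + 1) - Gp(b + 1, a) + Gp(a, a);
  return L - S / L;
}

// Exact minimization of the variance criterion for K = 0..Kmax change points
// by dynamic programming over suffixes; ties broken toward the
// lexicographically smallest boundary vector. Boundaries are reported
// 1-based as the last window of each phase.
// [[Rcpp::export]]
List cpp_kcp_segment(const arma::mat& G, const int kmax, const int min_phase) {
  const int w = G.n_rows;
  if (kmax >= w) stop("Kmax must be smaller than the number of windows");
  if (min_phase < 1) stop("min_phase must be >= 1");
  if ((kmax + 1) * min_phase > w)
    stop("Kmax and min_phase leave no admissible segmentation");

  // prefix sums: Gp(i, j) = sum of G[0..i-1, 0..j-1]
  arma::mat Gp(w + 1, w + 1, arma::fill::zeros);
  for (int i = 0; i < w; ++i) {
    double row = 0;
    for (int j = 0; j < w; ++j) {
      row += G(i, j);
      Gp(i + 1, j + 1) = Gp(i, j + 1) + row;
    }
  }

  const int M = kmax + 1;  // max number of phases
  // S(m-1, s): minimal total scatter of partitioning windows s..w-1 into m
  // phases, each of >= min_phase windows; INF where infeasible.
  const double INF = arma::datum::inf;
  arma::mat S(M, w + 1);
  S.fill(INF);
  for (int s = w - min_phase; s >= 0; --s) S(0, s) = seg_cost(Gp, s, w - 1);
  for (int m = 2; m <= M; ++m) {
    // first phase covers s..e, remainder needs (m-1)*min_phase windows
    for (int s = 0; s + m * min_phase <= w; ++s) {
      double best = INF;
      const int e_lo = s + min_phase - 1;
      const int e_hi = w - (m - 1) * min_phase - 1;
      for (int e = e_lo; e <= e_hi; ++e) {
        const double v = seg_cost(Gp, s, e) + S(m - 2, e + 1);
        if (v < best) best = v;
      }
      S(m - 1, s) = best;
    }
  }

  NumericVector rmin(M);
  List bounds(M);
  for (int K = 0; K < M; ++K) {
    rmin[K] = S(K, 0) / w;
    IntegerVector tau(K);
    int s = 0;
    for (int m = K + 1; m >= 2; --m) {
      const double target = S(m - 1, s);
      const int e_lo = s + min_phase - 1;
      const int e_hi = w - (m - 1) * min_phase - 1;
      int pick = -1;
      for (int e = e_lo; e <= e_hi; ++e) {
        if (seg_cost(Gp, s, e) + S(m - 2, e + 1) == target) { pick = e; break; }
      }
      if (pick < 0) stop("internal error: DP reconstruction failed");
      tau[K + 1 - m] = pick + 1;  // 1-based last window of the phase
      s = pick + 1;
    }
    bounds[K] = tau;
  }
  return List::create(_["rmin"] = rmin, _["boundaries"] = bounds);
}

// One full pipeline evaluation used by the permutation test: running
// autocorrelations of X, median bandwidth, kernel, rmin for K = 0..Kmax and
// the maximal variance drop. Returns NA if the derived series is degenerate
// (constant window or zero bandwidth) so the caller can redraw.
// [[Rcpp::export]]
double cpp_max_variance_drop(const arma::mat& X, const int window,
                             const int kmax, const int min_phase) {
  arma::mat P = cpp_running_autocor(X, window);
  if (!P.is_finite()) return NA_REAL;
  double h = cpp_median_bandwidth(P);
  if (!(h > 0)) return NA_REAL;
  arma::mat G = cpp_kernel_matrix(P, h);
  List seg = cpp_kcp_segment(G, kmax, min_phase);
  NumericVector rmin = seg["rmin"];
  double best = -arma::datum::inf;
  for (int K = 1; K <= kmax; ++K) {
    const double drop = rmin[K - 1] - rmin[K];
    if (drop > best) best = drop;
  }
  return best;
}
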