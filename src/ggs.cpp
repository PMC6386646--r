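// Inner kernels for greedy Gaussian segmentation.
//
// All segment statistics are read off prefix sums so that the
// log-likelihood of any segment [s, e) costs one m x m Cholesky,
// independent of segment length.  `cx` holds (T+1) x m cumulative sums
// of the data, `cxx` (T+1) x m^2 cumulative sums of the outer products
// x_t x_t'.  Indices s, e are 0-based and half-open, as in the R layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Gaussian log-likelihood of segment [s, e) at the plug-in mean and the
// regularized covariance  Sigma = S + (lambda/n) I  (S the biased sample
// covariance).  tr(Sigma^-1 S) = m - (lambda/n) tr(Sigma^-1).
static double seg_psi(const mat& cx, const mat& cxx, const int s, const int e,
                      const double lambda) {
  const int m = cx.n_cols;
  const double n = static_cast<double>(e - s);
  rowvec mu = (cx.row(e) - cx.row(s)) / n;
  rowvec d = cxx.row(e) - cxx.row(s);
  mat S(const_cast<double*>(d.memptr()), m, m);   // row-major == col-major: symmetric
  S = S / n - mu.t() * mu;
  S = 0.5 * (S + S.t());
  mat Sig = S;
  Sig.diag() += lambda / n;
  mat R;
  if (!chol(R, Sig)) return -datum::inf;
  const double logdet = 2.0 * accu(log(R.diag()));
  double tr_term = m;
  if (lambda > 0.0) {
    mat Rinv = inv(trimatu(R));
    tr_term = m - (lambda / n) * accu(square(Rinv));  // tr(Sig^-1) = ||R^-1||_F^2
  }
  return -0.5 * n * (m * std::log(2.0 * M_PI) + logdet + tr_term);
}

// [[Rcpp::export]]
double ggs_psi_cpp(const arma::mat& cx, const arma::mat& cxx, const int s,
                   const int e, const double lambda) {
  return seg_psi(cx, cxx, s, e, lambda);
}

// Best single split of segment [s, e): maximizes psi(s,t) + psi(t,e) over
// admissible t.  Ties resolved toward the smallest index (strict >).
// Returns (t, gain, psi_left + psi_right); t = -1 when no admissible split.
// [[Rcpp::export]]
Rcpp::NumericVector ggs_best_split_cpp(const arma::mat& cx, const arma::mat& cxx,
                                       const int s, const int e,
                                       const int min_len, const double lambda) {
  double best = -datum::inf;
  int best_t = -1;
  for (int t = s + min_len; t <= e - min_len; ++t) {
    const double v = seg_psi(cx, cxx, s, t, lambda) + seg_psi(cx, cxx, t, e, lambda);
    if (v > best) { best = v; best_t = t; }
  }
  Rcpp::NumericVector out(3);
  if (best_t < 0) {
    out[0] = -1; out[1] = -datum::inf; out[2] = -datum::inf;
    return out;
  }
  const double whole = seg_psi(cx, cxx, s, e, lambda);
  out[0] = best_t;
  out[1] = best - whole;
  out[2] = best;
  return out;
}
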