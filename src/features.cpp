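// Per-segment statistical features.
//
// For each segment and channel, six statistics (mean, sd, median absolute
// deviation, min, max, entropy of absolute values) on the raw samples and
// on the one-sided magnitude spectrum of the mean-removed samples (DC bin
// included).  Output layout matches the R fallback: time-domain block
// first (channel-major, six stats per channel), then the frequency-domain
// block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void six_stats(const vec& v, double* out) {
  const uword n = v.n_elem;
  const double mu = mean(v);
  out[0] = mu;
  out[1] = n > 1 ? std::sqrt(accu(square(v - mu)) / (n - 1)) : 0.0;
  const double med = median(v);
  out[2] = median(abs(v - med));
  out[3] = v.min();
  out[4] = v.max();
  const vec a = abs(v);
  const double s = accu(a);
  double ent = 0.0;
  if (s > 0.0) {
    for (uword i = 0; i < n; ++i) {
      const double p = a(i) / s;
      if (p > 0.0) ent -= p * std::log(p);
    }
  }
  out[5] = ent;
}

// [[Rcpp::export]]
arma::mat segment_features_cpp(const arma::mat& X, const arma::ivec& starts,
                               const arma::ivec& ends) {
  const uword m = X.n_cols;
  const uword nseg = starts.n_elem;
  mat out(nseg, 12 * m);
  for (uword i = 0; i < nseg; ++i) {   // segments x (time block, freq block)
    const uword s = starts(i), e = ends(i);
    double st[6];
    for (uword j = 0; j < m; ++j) {
      const vec v = X(span(s, e - 1), span(j, j));
      six_stats(v, st);
      for (int k = 0; k < 6; ++k) out(i, j * 6 + k) = st[k];
      const cx_vec F = fft(v - mean(v));
      const uword nf = (e - s) / 2 + 1;
      const vec mag = abs(F.head(nf));
      six_stats(mag, st);
      for (int k = 0; k < 6; ++k) out(i, 6 * m + j * 6 + k) = st[k];
    }
  }
  return out;
}
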