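// Direct-form II transposed IIR filtering with explicit initial state,
// the building block of the zero-phase (forward-backward) filter.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector iir_df2t_cpp(const NumericVector& b, const NumericVector& a,
                           const NumericVector& x, const NumericVector& zi) {
  const int nb = b.size();
  const int n = x.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());   // length nb - 1
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nb > 1 ? z[0] : 0.0);
    for (int k = 0; k < nb - 2; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    if (nb > 1) z[nb - 2] = b[nb - 1] * xi - a[nb - 1] * yi;
    y[i] = yi;
  }
  return y;
}
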