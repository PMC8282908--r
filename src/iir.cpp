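#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Direct-form II transposed IIR filter with zero initial conditions:
//   y[n] = (b0 x[n] + w1) ; wk updated with b, a taps.
// Coefficients are normalized by a[0] here so callers can pass raw designs.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int n = x.size();
  const int nb = b.size();
  const int na = a.size();
  const int nw = std::max(nb, na) - 1;
  const double a0 = a[0];
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0), w(nw, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xn = x[i];
    const double yn = bb[0] * xn + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k) {
      w[k] = bb[k + 1] * xn + w[k + 1] - aa[k + 1] * yn;
    }
    if (nw > 0) w[nw - 1] = bb[nw] * xn - aa[nw] * yn;
    y[i] = yn;
  }
  return y;
}
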