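#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed, zero initial
// state. sos is L x 6 (b0 b1 b2 a0 a1 a2), a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int n = x.size(), L = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < L; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// 1-D non-local means. For sample t the candidates are t+d, d in
// [-search/2, search/2]; patch distance is the mean squared difference over a
// centered window of length `patch` (edges truncated symmetrically); weights
// w = exp(-d2 / h^2), normalized to sum to 1.
// [[Rcpp::export]]
NumericVector nlm1d_cpp(NumericVector x, int patch, int search, double h) {
  int n = x.size();
  int pr = patch / 2, sr = search / 2;
  NumericVector out(n);
  double h2 = h * h;
  if (h2 <= 0) h2 = 1e-300;
  for (int t = 0; t < n; ++t) {
    double wsum = 0.0, acc = 0.0;
    int lo = std::max(0, t - sr), hi = std::min(n - 1, t + sr);
    for (int s = lo; s <= hi; ++s) {
      // symmetric truncation keeps patches comparable near the edges
      int m = pr;
      if (t - m < 0) m = t;
      if (t + m > n - 1) m = n - 1 - t;
      if (s - m < 0) m = std::min(m, s);
      if (s + m > n - 1) m = std::min(m, n - 1 - s);
      double d2 = 0.0;
      for (int k = -m; k <= m; ++k) {
        double diff = x[t + k] - x[s + k];
        d2 += diff * diff;
      }
      d2 /= (2 * m + 1);
      double w = std::exp(-d2 / h2);
      wsum += w;
      acc += w * x[s];
    }
    out[t] = acc / wsum;
  }
  return out;
}
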