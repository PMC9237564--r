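#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections (direct form II transposed), zero initial
// conditions, applied down the rows of x (samples x series).
// sos: n_sections x 6 (b0 b1 b2 a0 a1 a2), a0 assumed 1.
// [[Rcpp::export]]
NumericMatrix sosfilt_cpp(NumericMatrix sos, NumericMatrix x) {
  int ns = sos.nrow(), n = x.nrow(), m = x.ncol();
  NumericMatrix y(clone(x));
  for (int j = 0; j < m; ++j) {
    for (int s = 0; s < ns; ++s) {
      double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double xi = y(i, j);
        double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        y(i, j) = yi;
      }
    }
  }
  return y;
}
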