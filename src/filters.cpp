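#include <Rcpp.h>
using namespace Rcpp;

// Cascaded-biquad (second-order sections) causal IIR filtering with
// carried state, direct form II transposed. `sos` is K x 6 with rows
// (b0, b1, b2, a0, a1, a2), a0 normalized to 1. `zi` is K x 2 and holds
// the per-section state so a stream can be filtered chunk by chunk with
// results identical to filtering it in one pass.
// [[Rcpp::export]]
List sosfilt_state(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int K = sos.nrow();
  const int n = x.size();
  NumericVector y = clone(x);
  NumericMatrix z = clone(zi);
  for (int k = 0; k < K; ++k) {
    const double b0 = sos(k, 0), b1 = sos(k, 1), b2 = sos(k, 2);
    const double a1 = sos(k, 4), a2 = sos(k, 5);
    double z1 = z(k, 0), z2 = z(k, 1);
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
    z(k, 0) = z1;
    z(k, 1) = z2;
  }
  return List::create(_["y"] = y, _["zi"] = z);
}
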