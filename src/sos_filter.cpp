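#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One pass of a biquad cascade (direct form II transposed), in place.
// With steady_init, each section starts in its steady state for a constant
// input equal to the first sample, which suppresses startup transients in
// zero-phase (forward-backward) use.
static void sosfilt_inplace(const NumericMatrix& sos, std::vector<double>& x,
                            bool steady_init) {
  const int ns = sos.nrow();
  const int n = (int)x.size();
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;
    if (steady_init && n > 0) {
      const double g = (b0 + b1 + b2) / (1.0 + a1 + a2);
      w1 = (g - b0) * x[0];
      w2 = (b2 - a2 * g) * x[0];
    }
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
  }
}

// Zero-phase (forward-backward) biquad-cascade filtering of each row of X,
// with even-symmetric reflection padding of padlen samples at both ends.
// sos rows are (b0, b1, b2, a0, a1, a2) with a0 == 1.
// [[Rcpp::export(name = ".sos_filtfilt_mat")]]
NumericMatrix sos_filtfilt_mat(NumericMatrix sos, NumericMatrix X, int padlen) {
  const int ntr = X.nrow(), n = X.ncol();
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  NumericMatrix out(ntr, n);
  std::vector<double> ext(n + 2 * padlen);
  for (int r = 0; r < ntr; ++r) {
    for (int i = 0; i < padlen; ++i) ext[i] = X(r, padlen - i);
    for (int i = 0; i < n; ++i) ext[padlen + i] = X(r, i);
    for (int i = 0; i < padlen; ++i) ext[padlen + n + i] = X(r, n - 2 - i);
    sosfilt_inplace(sos, ext, true);
    std::reverse(ext.begin(), ext.end());
    sosfilt_inplace(sos, ext, true);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; ++i) out(r, i) = ext[padlen + i];
  }
  return out;
}

// Single forward pass over each row (one-pass filtering, zero initial
// state, no padding).
// [[Rcpp::export(name = ".sos_filter_mat")]]
NumericMatrix sos_filter_mat(NumericMatrix sos, NumericMatrix X) {
  const int ntr = X.nrow(), n = X.ncol();
  NumericMatrix out(ntr, n);
  std::vector<double> buf(n);
  for (int r = 0; r < ntr; ++r) {
    for (int i = 0; i < n; ++i) buf[i] = X(r, i);
    sosfilt_inplace(sos, buf, false);
    for (int i = 0; i < n; ++i) out(r, i) = buf[i];
  }
  return out;
}
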