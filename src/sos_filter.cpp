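#include <Rcpp.h>
using namespace Rcpp;

// Run a cascade of biquad sections (direct form II transposed) forward over
// each column of x. Coefficients: one row per section, b (3 cols) and a
// (3 cols, a[,0] == 1). The initial state of each section is the
// steady-state response to a step of the section input's first sample,
// which suppresses startup transients (the filtfilt convention).
// [[Rcpp::export(name = ".sos_filt_mat")]]
NumericMatrix sos_filt_mat(NumericMatrix x, NumericMatrix b, NumericMatrix a) {
  const int n = x.nrow(), m = x.ncol(), ns = b.nrow();
  NumericMatrix y(n, m);
  std::vector<double> v(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) v[i] = x(i, j);
    for (int s = 0; s < ns; ++s) {
      const double b0 = b(s, 0), b1 = b(s, 1), b2 = b(s, 2);
      const double a1 = a(s, 1), a2 = a(s, 2);
      const double gdc = (b0 + b1 + b2) / (1.0 + a1 + a2);
      const double x0 = v[0];
      double z1 = (gdc - b0) * x0;
      double z2 = (b2 - a2 * gdc) * x0;
      for (int i = 0; i < n; ++i) {
        const double xi = v[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        v[i] = yi;
      }
    }
    for (int i = 0; i < n; ++i) y(i, j) = v[i];
  }
  return y;
}
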