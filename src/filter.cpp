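#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter; a[0] must be 1.
static void df2_inplace(const std::vector<double>& b,
                        const std::vector<double>& a,
                        std::vector<double>& x) {
  int nz = (int)std::max(b.size(), a.size()) - 1;
  std::vector<double> z(nz + 1, 0.0);
  std::vector<double> bp(nz + 1, 0.0), ap(nz + 1, 0.0);
  for (size_t j = 0; j < b.size(); ++j) bp[j] = b[j];
  for (size_t j = 0; j < a.size(); ++j) ap[j] = a[j];
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bp[0] * xi + z[0];
    for (int j = 1; j <= nz; ++j)
      z[j - 1] = bp[j] * xi - ap[j] * yi + z[j];
    x[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector df2_filter(NumericVector b, NumericVector a, NumericVector x) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end()),
      xx(x.begin(), x.end());
  df2_inplace(bb, aa, xx);
  return wrap(xx);
}

// Forward-backward (zero-phase) IIR filtering with reflective edge padding.
// [[Rcpp::export]]
NumericVector zero_phase_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int n = x.size();
  // generous reflective padding lets the zero-state transient decay below
  // machine precision before the signal proper begins
  const int np = std::min(std::max(250, 3 * ((int)std::max(b.size(), a.size()) - 1)),
                          n - 1);
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  std::vector<double> xp(n + 2 * np);
  for (int i = 0; i < np; ++i) xp[i] = 2.0 * x[0] - x[np - i];
  for (int i = 0; i < n; ++i) xp[np + i] = x[i];
  for (int i = 0; i < np; ++i) xp[np + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  df2_inplace(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());
  df2_inplace(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = xp[np + i];
  return y;
}

// Cubic-convolution (Keys, a = -1/2) interpolation of x (0-based uniform
// grid) at positions pos; edge neighbors clamped.
// [[Rcpp::export]]
NumericVector keys_interp(NumericVector x, NumericVector pos) {
  const int n = x.size(), m = pos.size();
  NumericVector y(m);
  for (int i = 0; i < m; ++i) {
    const double p = pos[i];
    int k = (int)std::floor(p);
    const double f = p - k;
    auto at = [&](int d) {
      int j = k + d;
      if (j < 0) j = 0;
      if (j > n - 1) j = n - 1;
      return x[j];
    };
    const double w0 = ((-0.5 * f + 1.0) * f - 0.5) * f;
    const double w1 = ((1.5 * f - 2.5) * f) * f + 1.0;
    const double w2 = ((-1.5 * f + 2.0) * f + 0.5) * f;
    const double w3 = (0.5 * f - 0.5) * f * f;
    y[i] = w0 * at(-1) + w1 * at(0) + w2 * at(1) + w3 * at(2);
  }
  return y;
}
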