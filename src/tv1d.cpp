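#include <Rcpp.h>
using namespace Rcpp;

// Exact proximal operator of lambda * TV_1D (taut-string / direct algorithm):
// minimizes 0.5*||x - y||^2 + lambda * sum_k |x_{k+1} - x_k|.
// 0-based translation of the classic direct algorithm's pseudocode.
static void tv1d_prox(const double* y, double* x, int n, double lambda) {
  if (n <= 0) return;
  if (n == 1 || lambda <= 0.0) {
    for (int i = 0; i < n; ++i) x[i] = y[i];
    return;
  }
  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lambda, vmax = y[0] + lambda;
  double umin = lambda, umax = -lambda;

  for (;;) {
    if (k == n - 1) { // boundary handling at the last sample
      if (umin < 0.0) {
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k = k0 = km = km + 1;
        vmin = y[k];
        umin = lambda;
        umax = y[k] + lambda - vmax;
        if (k == n - 1) { x[n - 1] = vmin + umin; return; }
        continue;
      } else if (umax > 0.0) {
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k = k0 = kp = kp + 1;
        vmax = y[k];
        umax = -lambda;
        umin = y[k] - lambda - vmin;
        if (k == n - 1) { x[n - 1] = vmin + umin; return; }
        continue;
      } else {
        const double v = vmin + umin / (k - k0 + 1);
        for (int i = k0; i <= n - 1; ++i) x[i] = v;
        return;
      }
    }
    if (y[k + 1] + umin < vmin - lambda) { // negative jump
      for (int i = k0; i <= km; ++i) x[i] = vmin;
      k = k0 = km = kp = km + 1;
      vmin = y[k];
      vmax = y[k] + 2.0 * lambda;
      umin = lambda;
      umax = -lambda;
    } else if (y[k + 1] + umax > vmax + lambda) { // positive jump
      for (int i = k0; i <= kp; ++i) x[i] = vmax;
      k = k0 = km = kp = kp + 1;
      vmin = y[k] - 2.0 * lambda;
      vmax = y[k];
      umin = lambda;
      umax = -lambda;
    } else { // no jump: extend the current segment
      k = k + 1;
      umin += y[k] - vmin;
      umax += y[k] - vmax;
      if (umin >= lambda) {
        vmin += (umin - lambda) / (k - k0 + 1);
        umin = lambda;
        km = k;
      }
      if (umax <= -lambda) {
        vmax += (umax + lambda) / (k - k0 + 1);
        umax = -lambda;
        kp = k;
      }
    }
  }
}

// Apply the 1D TV prox down each column (the phase-encode direction).
// [[Rcpp::export]]
NumericMatrix tv1d_prox_cols_cpp(const NumericMatrix& y, double lambda) {
  const int ny = y.nrow(), nx = y.ncol();
  NumericMatrix x(ny, nx);
  std::vector<double> col(ny), res(ny);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) col[i] = y(i, j);
    tv1d_prox(col.data(), res.data(), ny, lambda);
    for (int i = 0; i < ny; ++i) x(i, j) = res[i];
  }
  return x;
}
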