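#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Non-local means denoising for Gaussian noise of known sd sigma.
// Patch similarity uses the mean squared difference over (2f+1)^2 patches,
// noise-compensated by 2*sigma^2; weights are exp(-max(d2 - 2sigma^2, 0)/h^2)
// with h = k * sigma. The self-weight is set to the maximum neighbor weight.
// Borders are handled by clamping patch coordinates to the image.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(const NumericMatrix& img, double sigma,
                              int patch_radius = 2, int search_radius = 5,
                              double h_factor = 0.4) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  if (sigma <= 0.0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  const double h2 = std::pow(h_factor * sigma, 2.0);
  const double two_s2 = 2.0 * sigma * sigma;
  const int f = patch_radius, t = search_radius;
  const double npatch = std::pow(2.0 * f + 1.0, 2.0);

  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double wsum = 0.0, acc = 0.0, wmax = 0.0;
      for (int dj = -t; dj <= t; ++dj) {
        const int j2 = j + dj;
        if (j2 < 0 || j2 >= nx) continue;
        for (int di = -t; di <= t; ++di) {
          const int i2 = i + di;
          if (i2 < 0 || i2 >= ny) continue;
          if (di == 0 && dj == 0) continue;
          // clamped patch squared distance
          double d2 = 0.0;
          for (int pj = -f; pj <= f; ++pj) {
            int ja = std::min(std::max(j + pj, 0), nx - 1);
            int jb = std::min(std::max(j2 + pj, 0), nx - 1);
            for (int pi = -f; pi <= f; ++pi) {
              int ia = std::min(std::max(i + pi, 0), ny - 1);
              int ib = std::min(std::max(i2 + pi, 0), ny - 1);
              const double diff = img(ia, ja) - img(ib, jb);
              d2 += diff * diff;
            }
          }
          d2 /= npatch;
          double w = std::exp(-std::max(d2 - two_s2, 0.0) / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          acc += w * img(i2, j2);
        }
      }
      // self weight: max of the neighbor weights (or 1 if isolated)
      const double wself = (wmax > 0.0) ? wmax : 1.0;
      wsum += wself;
      acc += wself * img(i, j);
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
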