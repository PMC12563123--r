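// Tensor-product trapezoid quadrature of the information functionals of an
// isotropic Gaussian-mixture density. Exploits separability: each component
// contributes an outer product of three 1D Gaussian factors, and components
// whose x-y factor product is already negligible are skipped in the inner
// z loop.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double RHO_FLOOR = 1e-300;
static const double FACTOR_FLOOR = 1e-280;

// Returns c(mass, S, I, D); I is NA when need_gradient is false.
// [[Rcpp::export(name = ".quad_level_cpp")]]
NumericVector quad_level_cpp(NumericMatrix centers, NumericVector sigmas,
                             NumericVector weights, NumericVector lo,
                             NumericVector hi, int n, bool need_gradient) {
  const int nc = sigmas.size();
  std::vector<double> h(3);
  for (int k = 0; k < 3; ++k) h[k] = (hi[k] - lo[k]) / (n - 1);

  // per-component 1D Gaussian factors and gradient prefactors per axis
  // fx carries the component weight; fy, fz carry only the 1D normalisation
  std::vector<double> fx(nc * n), fy(nc * n), fz(nc * n);
  std::vector<double> dx(nc * n), dy(nc * n), dz(nc * n);
  for (int c = 0; c < nc; ++c) {
    const double s2 = sigmas[c] * sigmas[c];
    const double norm1 = 1.0 / std::sqrt(2.0 * M_PI * s2);
    for (int i = 0; i < n; ++i) {
      const double x = lo[0] + h[0] * i;
      const double y = lo[1] + h[1] * i;
      const double z = lo[2] + h[2] * i;
      fx[c * n + i] = weights[c] * norm1 *
                      std::exp(-(x - centers(c, 0)) * (x - centers(c, 0)) /
                               (2.0 * s2));
      fy[c * n + i] = norm1 *
                      std::exp(-(y - centers(c, 1)) * (y - centers(c, 1)) /
                               (2.0 * s2));
      fz[c * n + i] = norm1 *
                      std::exp(-(z - centers(c, 2)) * (z - centers(c, 2)) /
                               (2.0 * s2));
      dx[c * n + i] = (centers(c, 0) - x) / s2;
      dy[c * n + i] = (centers(c, 1) - y) / s2;
      dz[c * n + i] = (centers(c, 2) - z) / s2;
    }
  }

  double mass = 0.0, S = 0.0, I = 0.0, D = 0.0;
  std::vector<double> fxy(nc);
  std::vector<int> active(nc);
  for (int ix = 0; ix < n; ++ix) {
    const double wx = (ix == 0 || ix == n - 1) ? 0.5 : 1.0;
    for (int iy = 0; iy < n; ++iy) {
      const double wxy = wx * ((iy == 0 || iy == n - 1) ? 0.5 : 1.0);
      int na = 0;
      for (int c = 0; c < nc; ++c) {
        const double v = fx[c * n + ix] * fy[c * n + iy];
        if (v > FACTOR_FLOOR) {
          fxy[na] = v;
          active[na++] = c;
        }
      }
      if (na == 0) continue;
      for (int iz = 0; iz < n; ++iz) {
        double rho = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
        for (int a = 0; a < na; ++a) {
          const int c = active[a];
          const double t = fxy[a] * fz[c * n + iz];
          rho += t;
          if (need_gradient) {
            gx += t * dx[c * n + ix];
            gy += t * dy[c * n + iy];
            gz += t * dz[c * n + iz];
          }
        }
        if (rho <= RHO_FLOOR) continue;
        const double w = wxy * ((iz == 0 || iz == n - 1) ? 0.5 : 1.0);
        mass += w * rho;
        S -= w * rho * std::log(rho);
        D += w * rho * rho;
        if (need_gradient) I += w * (gx * gx + gy * gy + gz * gz) / rho;
      }
    }
  }
  const double voxel = h[0] * h[1] * h[2];
  NumericVector out = NumericVector::create(
      _["mass"] = mass * voxel, _["S"] = S * voxel,
      _["I"] = need_gradient ? I * voxel : NA_REAL, _["D"] = D * voxel);
  return out;
}
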