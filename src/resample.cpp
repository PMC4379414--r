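// Resampling and mean-squares metric for the registration stack.
// A transform maps fixed-image voxel coordinates x (0-based) to moving-image
// coordinates: T(x) = A (x - c) + c + t + U(x), where U is a displacement
// field interpolated multilinearly from a control-point grid spanning the
// fixed domain (free-form deformation); U is absent when the grid is empty.
// Moving intensities are sampled with linear interpolation, coordinates
// clamped to the moving domain (edge replication).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  const double* v; int n[3]; int d;  // n = grid dims (unused axes 1)
  double sp[3];                      // grid spacing in fixed voxels
};

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// multilinear interpolation of a scalar field (nx,ny,nz), clamped
inline double interp(const double* img, int nx, int ny, int nz,
                     double x, double y, double z) {
  x = clampd(x, 0, nx - 1.0); y = clampd(y, 0, ny - 1.0); z = clampd(z, 0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1 && nx > 1) x0--;
  if (y0 == ny - 1 && ny > 1) y0--;
  if (z0 == nz - 1 && nz > 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  auto at = [&](int X, int Y, int Z) { return img[X + nx * (Y + ny * Z)]; };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

}  // namespace

// Warp the moving image onto the fixed grid under (A, t, center, ctrl).
// fdim/mdim: length-3 dims (nz = 1 for 2D). A: d*d column-major. ctrl:
// control displacements, dims (g1,g2,g3,d) with g3 = 1 in 2D; empty = none.
// [[Rcpp::export]]
NumericVector cpp_warp(const NumericVector& moving, const IntegerVector& mdim,
                       const IntegerVector& fdim, const NumericVector& A,
                       const NumericVector& t, const NumericVector& center,
                       const NumericVector& ctrl, const IntegerVector& gdim,
                       int nearest) {
  int d = t.size();
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  int mx = mdim[0], my = mdim[1], mz = mdim[2];
  bool hasU = ctrl.size() > 0;
  int g[3] = { 1, 1, 1 };
  double gs[3] = { 1, 1, 1 };
  if (hasU) {
    for (int k = 0; k < d; ++k) {
      g[k] = gdim[k];
      gs[k] = (g[k] > 1) ? (double)(fdim[k] - 1) / (g[k] - 1) : 1.0;
    }
  }
  size_t gstride = (size_t)g[0] * g[1] * g[2];
  NumericVector out((R_xlen_t)fx * fy * fz);
  std::vector<double> mv(moving.begin(), moving.end());
  for (int z = 0; z < fz; ++z)
    for (int y = 0; y < fy; ++y)
      for (int x = 0; x < fx; ++x) {
        double xc[3] = { (double)x, (double)y, (double)z };
        double p[3] = { 0, 0, 0 };
        for (int r = 0; r < d; ++r) {
          double acc = center[r] + t[r];
          for (int c = 0; c < d; ++c) acc += A[r + d * c] * (xc[c] - center[c]);
          p[r] = acc;
        }
        if (d == 2) p[2] = 0;
        if (hasU) {
          // displacement interpolated on the control grid
          double gx = xc[0] / gs[0], gy = xc[1] / gs[1],
                 gz = (d == 3) ? xc[2] / gs[2] : 0.0;
          for (int comp = 0; comp < d; ++comp)
            p[comp] += interp(&ctrl[0] + comp * gstride, g[0], g[1], g[2], gx, gy, gz);
        }
        if (nearest)
          for (int k = 0; k < 3; ++k) p[k] = std::round(p[k]);
        out[x + (R_xlen_t)fx * (y + (R_xlen_t)fy * z)] =
          interp(mv.data(), mx, my, mz, p[0], p[1], p[2]);
      }
  return out;
}

// Mean-squared intensity difference between the fixed image and the warped
// moving image over the whole fixed domain.
// [[Rcpp::export]]
double cpp_mse(const NumericVector& fixed, const NumericVector& moving,
               const IntegerVector& mdim, const IntegerVector& fdim,
               const NumericVector& A, const NumericVector& t,
               const NumericVector& center, const NumericVector& ctrl,
               const IntegerVector& gdim, int stride) {
  int d = t.size();
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  int mx = mdim[0], my = mdim[1], mz = mdim[2];
  bool hasU = ctrl.size() > 0;
  int g[3] = { 1, 1, 1 };
  double gs[3] = { 1, 1, 1 };
  if (hasU)
    for (int k = 0; k < d; ++k) {
      g[k] = gdim[k];
      gs[k] = (g[k] > 1) ? (double)(fdim[k] - 1) / (g[k] - 1) : 1.0;
    }
  size_t gstride = (size_t)g[0] * g[1] * g[2];
  std::vector<double> mv(moving.begin(), moving.end());
  if (stride < 1) stride = 1;
  double s = 0; R_xlen_t n = 0;
  for (int z = 0; z < fz; z += (fz > 1 ? stride : 1))
    for (int y = 0; y < fy; y += stride)
      for (int x = 0; x < fx; x += stride) {
        double xc[3] = { (double)x, (double)y, (double)z };
        double p[3] = { 0, 0, 0 };
        for (int r = 0; r < d; ++r) {
          double acc = center[r] + t[r];
          for (int c = 0; c < d; ++c) acc += A[r + d * c] * (xc[c] - center[c]);
          p[r] = acc;
        }
        if (d == 2) p[2] = 0;
        if (hasU) {
          double gx = xc[0] / gs[0], gy = xc[1] / gs[1],
                 gz = (d == 3) ? xc[2] / gs[2] : 0.0;
          for (int comp = 0; comp < d; ++comp)
            p[comp] += interp(&ctrl[0] + comp * gstride, g[0], g[1], g[2], gx, gy, gz);
        }
        double val = interp(mv.data(), mx, my, mz, p[0], p[1], p[2]);
        double r2 = val - fixed[x + (R_xlen_t)fx * (y + (R_xlen_t)fy * z)];
        s += r2 * r2; ++n;
      }
  return s / n;
}

// Mean-squares metric and its analytic gradient with respect to the control
// displacements (affine part held fixed). The moving-image gradient at the
// mapped point is taken by central differences of the interpolant.
// [[Rcpp::export]]
List cpp_ffd_mse_grad(const NumericVector& fixed, const NumericVector& moving,
                      const IntegerVector& mdim, const IntegerVector& fdim,
                      const NumericVector& A, const NumericVector& t,
                      const NumericVector& center, const NumericVector& ctrl,
                      const IntegerVector& gdim, int stride) {
  if (stride < 1) stride = 1;
  int d = t.size();
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  int mx = mdim[0], my = mdim[1], mz = mdim[2];
  int g[3] = { 1, 1, 1 };
  double gs[3] = { 1, 1, 1 };
  for (int k = 0; k < d; ++k) {
    g[k] = gdim[k];
    gs[k] = (g[k] > 1) ? (double)(fdim[k] - 1) / (g[k] - 1) : 1.0;
  }
  size_t gstride = (size_t)g[0] * g[1] * g[2];
  NumericVector grad(ctrl.size());
  std::vector<double> mv(moving.begin(), moving.end());
  double mse = 0;
  R_xlen_t N = 0;
  for (int z = 0; z < fz; z += (fz > 1 ? stride : 1))
    for (int y = 0; y < fy; y += stride)
      for (int x = 0; x < fx; x += stride) {
        ++N;
        double xc[3] = { (double)x, (double)y, (double)z };
        double p[3] = { 0, 0, 0 };
        for (int r = 0; r < d; ++r) {
          double acc = center[r] + t[r];
          for (int c = 0; c < d; ++c) acc += A[r + d * c] * (xc[c] - center[c]);
          p[r] = acc;
        }
        if (d == 2) p[2] = 0;
        double gx = xc[0] / gs[0], gy = xc[1] / gs[1],
               gz = (d == 3) ? xc[2] / gs[2] : 0.0;
        for (int comp = 0; comp < d; ++comp)
          p[comp] += interp(&ctrl[0] + comp * gstride, g[0], g[1], g[2], gx, gy, gz);
        double val = interp(mv.data(), mx, my, mz, p[0], p[1], p[2]);
        double F = fixed[x + (R_xlen_t)fx * (y + (R_xlen_t)fy * z)];
        double r2 = val - F;
        mse += r2 * r2;
        // moving-image gradient at p
        double gM[3] = { 0, 0, 0 };
        gM[0] = 0.5 * (interp(mv.data(), mx, my, mz, p[0] + 1, p[1], p[2]) -
                       interp(mv.data(), mx, my, mz, p[0] - 1, p[1], p[2]));
        gM[1] = 0.5 * (interp(mv.data(), mx, my, mz, p[0], p[1] + 1, p[2]) -
                       interp(mv.data(), mx, my, mz, p[0], p[1] - 1, p[2]));
        if (d == 3)
          gM[2] = 0.5 * (interp(mv.data(), mx, my, mz, p[0], p[1], p[2] + 1) -
                         interp(mv.data(), mx, my, mz, p[0], p[1], p[2] - 1));
        // multilinear weights to the surrounding control nodes
        double gc[3] = { clampd(gx, 0, g[0] - 1.0), clampd(gy, 0, g[1] - 1.0),
                         clampd(gz, 0, g[2] - 1.0) };
        int i0[3], i1[3]; double f[3];
        for (int k = 0; k < 3; ++k) {
          i0[k] = (int)std::floor(gc[k]);
          if (i0[k] == g[k] - 1 && g[k] > 1) i0[k]--;
          i1[k] = std::min(i0[k] + 1, g[k] - 1);
          f[k] = gc[k] - i0[k];
        }
        for (int cz = 0; cz <= (d == 3 ? 1 : 0); ++cz)
          for (int cy = 0; cy <= 1; ++cy)
            for (int cx = 0; cx <= 1; ++cx) {
              double w = (cx ? f[0] : 1 - f[0]) * (cy ? f[1] : 1 - f[1]) *
                         (d == 3 ? (cz ? f[2] : 1 - f[2]) : 1.0);
              if (w == 0) continue;
              int node = (cx ? i1[0] : i0[0]) +
                         g[0] * ((cy ? i1[1] : i0[1]) +
                                 g[1] * (cz ? i1[2] : i0[2]));
              for (int comp = 0; comp < d; ++comp)
                grad[node + comp * gstride] += 2.0 * r2 * gM[comp] * w;
            }
      }
  for (R_xlen_t i = 0; i < grad.size(); ++i) grad[i] /= N;
  return List::create(_["mse"] = mse / N, _["grad"] = grad);
}
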