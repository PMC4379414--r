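// Separable smoothing and Prewitt gradients with edge replication.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Convolve along one axis with a centered 3-tap kernel, edge replication.
static void conv3_axis(const std::vector<double>& in, std::vector<double>& out,
                       int nx, int ny, int nz, int axis, const double k[3]) {
  int n[3] = { nx, ny, nz };
  int stride[3] = { 1, nx, nx * ny };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int c[3] = { x, y, z };
        int i = x + nx * (y + ny * z);
        double acc = 0.0;
        for (int t = -1; t <= 1; ++t) {
          int cc = clampi(c[axis] + t, 0, n[axis] - 1);
          int j = i + (cc - c[axis]) * stride[axis];
          acc += k[t + 1] * in[j];
        }
        out[i] = acc;
      }
}

// Gaussian blur (3-tap, sigma = 0.5 voxel) followed by Prewitt gradient
// magnitude (Euclidean norm of per-axis components). For nz == 1 the
// computation is purely in-plane.
// [[Rcpp::export]]
NumericVector cpp_gradient_magnitude(const NumericVector& vol, int nx, int ny, int nz) {
  size_t N = (size_t)nx * ny * nz;
  std::vector<double> a(N), b(N);
  for (size_t i = 0; i < N; ++i) a[i] = vol[i];
  // sigma = 0.5: weights exp(0), exp(-2) normalized
  const double w = std::exp(-2.0);
  const double g[3] = { w / (1 + 2 * w), 1.0 / (1 + 2 * w), w / (1 + 2 * w) };
  int ndim = (nz > 1) ? 3 : 2;
  for (int ax = 0; ax < ndim; ++ax) { conv3_axis(a, b, nx, ny, nz, ax, g); a.swap(b); }
  // Prewitt: derivative [-1,0,1] along the axis, smoothing [1,1,1]/3 across
  const double d[3] = { -1.0, 0.0, 1.0 };
  const double s[3] = { 1.0 / 3, 1.0 / 3, 1.0 / 3 };
  NumericVector out(vol.size());
  std::vector<double> comp(N), tmp(N);
  for (int ax = 0; ax < ndim; ++ax) {
    std::copy(a.begin(), a.end(), comp.begin());
    for (int ax2 = 0; ax2 < ndim; ++ax2) {
      conv3_axis(comp, tmp, nx, ny, nz, ax2, ax2 == ax ? d : s);
      comp.swap(tmp);
    }
    for (size_t i = 0; i < N; ++i) out[i] += comp[i] * comp[i];
  }
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
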