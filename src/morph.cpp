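// Binary morphology, connected components, hole filling and chamfer
// distances on 2D/3D grids stored in R's column-major order.
// Conventions: face connectivity matches the unit-diamond structuring
// element; voxels outside the grid are background (pad = 0) unless the
// caller asks for foreground padding (pad = 1, used for exact duality).
#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// One unit (half-size 1) erosion or dilation.
// kind: 0 = diamond (face neighbours), 1 = square (full neighbourhood)
// twoD: restrict the element to the axial plane (applied slice-wise)
// [[Rcpp::export]]
LogicalVector cpp_morph_unit(const LogicalVector& mask, int nx, int ny, int nz,
                             bool erode, int kind, bool twoD, int pad) {
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        bool acc = erode;  // erosion: AND over element; dilation: OR
        int dzmax = twoD ? 0 : 1;
        for (int dz = -dzmax; dz <= dzmax && (erode ? acc : !acc); ++dz)
          for (int dy = -1; dy <= 1 && (erode ? acc : !acc); ++dy)
            for (int dx = -1; dx <= 1 && (erode ? acc : !acc); ++dx) {
              if (kind == 0 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
                continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              bool v;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                v = (pad != 0);
              else
                v = mask[idx3(X, Y, Z, nx, ny)];
              if (erode) acc = acc && v; else acc = acc || v;
            }
        out[i] = acc;
      }
  return out;
}

// Direct structuring element of half-size h (no iteration): diamond is the
// city-block ball, square the Chebyshev ball. Oracle path for the
// iterated-unit equivalence property.
// [[Rcpp::export]]
LogicalVector cpp_morph_direct(const LogicalVector& mask, int nx, int ny, int nz,
                               bool erode, int kind, int half, bool twoD, int pad) {
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        bool acc = erode;
        int dzmax = twoD ? 0 : half;
        for (int dz = -dzmax; dz <= dzmax && (erode ? acc : !acc); ++dz)
          for (int dy = -half; dy <= half && (erode ? acc : !acc); ++dy)
            for (int dx = -half; dx <= half && (erode ? acc : !acc); ++dx) {
              if (kind == 0 && std::abs(dx) + std::abs(dy) + std::abs(dz) > half)
                continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              bool v;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                v = (pad != 0);
              else
                v = mask[idx3(X, Y, Z, nx, ny)];
              if (erode) acc = acc && v; else acc = acc || v;
            }
        out[i] = acc;
      }
  return out;
}

// Flood-fill the background from the slice border; background components not
// reached become foreground. Strictly 2D, applied to every axial slice.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(const LogicalVector& mask, int nx, int ny, int nz) {
  LogicalVector out(mask.size());
  std::vector<char> reach((size_t)nx * ny);
  std::queue<int> q;
  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    int base = nx * ny * z;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x == 0 || y == 0 || x == nx - 1 || y == ny - 1) {
          int p = x + nx * y;
          if (!mask[base + p] && !reach[p]) { reach[p] = 1; q.push(p); }
        }
      }
    const int dx[4] = { -1, 1, 0, 0 }, dy[4] = { 0, 0, -1, 1 };
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int x = p % nx, y = p / nx;
      for (int k = 0; k < 4; ++k) {
        int X = x + dx[k], Y = y + dy[k];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny) continue;
        int pp = X + nx * Y;
        if (!mask[base + pp] && !reach[pp]) { reach[pp] = 1; q.push(pp); }
      }
    }
    for (int p = 0; p < nx * ny; ++p)
      out[base + p] = mask[base + p] || !reach[p];
  }
  return out;
}

// Connected components, labels assigned in increasing order of each
// component's smallest linear index (x fastest, then y, then z).
// full = 8/26-connectivity, otherwise face (4/6) connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label(const LogicalVector& mask, int nx, int ny, int nz, bool full) {
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < (int)mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (!full && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            int pp = idx3(X, Y, Z, nx, ny);
            if (mask[pp] && lab[pp] == 0) { lab[pp] = next; q.push(pp); }
          }
    }
  }
  return lab;
}

// City-block distance to the nearest background pixel, 2D two-pass chamfer.
// Background pixels get 0; the frame outside the image counts as background.
// [[Rcpp::export]]
IntegerVector cpp_cityblock_dt_2d(const LogicalVector& mask, int nx, int ny) {
  const int INF = nx + ny + 2;
  IntegerVector d(mask.size());
  for (int i = 0; i < (int)mask.size(); ++i) d[i] = mask[i] ? INF : 0;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int i = x + nx * y;
      if (d[i] == 0) continue;
      int best = d[i];
      best = std::min(best, (x > 0 ? d[i - 1] : 0) + 1);
      best = std::min(best, (y > 0 ? d[i - nx] : 0) + 1);
      d[i] = best;
    }
  for (int y = ny - 1; y >= 0; --y)
    for (int x = nx - 1; x >= 0; --x) {
      int i = x + nx * y;
      if (d[i] == 0) continue;
      int best = d[i];
      best = std::min(best, (x < nx - 1 ? d[i + 1] : 0) + 1);
      best = std::min(best, (y < ny - 1 ? d[i + nx] : 0) + 1);
      d[i] = best;
    }
  return d;
}

// Multi-source BFS fill: replaces NA cells of a matrix by the value of the
// nearest (city-block, FIFO ties) non-NA cell. Used to extrapolate bone
// envelopes over columns that contain no bone.
// [[Rcpp::export]]
NumericVector cpp_nearest_fill_2d(const NumericVector& vals, int nx, int ny) {
  NumericVector out = clone(vals);
  std::queue<int> q;
  std::vector<char> seen((size_t)nx * ny, 0);
  for (int i = 0; i < nx * ny; ++i)
    if (!NumericVector::is_na(out[i])) { seen[i] = 1; q.push(i); }
  const int dx[4] = { -1, 1, 0, 0 }, dy[4] = { 0, 0, -1, 1 };
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int x = p % nx, y = p / nx;
    for (int k = 0; k < 4; ++k) {
      int X = x + dx[k], Y = y + dy[k];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny) continue;
      int pp = X + nx * Y;
      if (!seen[pp]) { seen[pp] = 1; out[pp] = out[p]; q.push(pp); }
    }
  }
  return out;
}
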