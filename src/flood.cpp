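// Priority-queue flooding: watershed from markers and intensity-ordered
// marker growth. Both are fully deterministic: the queue is ordered by
// (priority, insertion counter) so equal-priority voxels are expanded in
// first-in-first-out order, and neighbours are always scanned in the fixed
// order -x, +x, -y, +y, -z, +z.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

struct WsItem {
  double v; long long c; int i; int lab;
};
struct WsCmp {  // min-heap on (v, c)
  bool operator()(const WsItem& a, const WsItem& b) const {
    if (a.v != b.v) return a.v > b.v;
    return a.c > b.c;
  }
};

// Watershed from markers on a relief (face connectivity). Marker voxels keep
// their labels; other voxels take the label of the basin that first reaches
// them in (relief, insertion order) flooding. With lines = true a voxel whose
// already-labelled face neighbours disagree at pop time becomes 0 instead.
// [[Rcpp::export]]
IntegerVector cpp_watershed(const NumericVector& relief, const IntegerVector& markers,
                            int nx, int ny, int nz, bool lines) {
  int N = nx * ny * nz;
  IntegerVector lab(N);
  std::vector<char> done((size_t)N, 0);
  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  long long counter = 0;
  for (int i = 0; i < N; ++i) {
    lab[i] = markers[i];
    if (markers[i] > 0) pq.push({ relief[i], counter++, i, markers[i] });
  }
  const int dx[6] = { -1, 1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, -1, 1, 0, 0 };
  const int dz[6] = { 0, 0, 0, 0, -1, 1 };
  while (!pq.empty()) {
    WsItem it = pq.top(); pq.pop();
    int i = it.i;
    if (done[i]) continue;
    done[i] = 1;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    int mylab;
    if (lab[i] != 0) {
      mylab = lab[i];
    } else if (lines) {
      int seen = 0; bool conflict = false;
      for (int k = 0; k < 6; ++k) {
        int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int l = lab[X + nx * (Y + ny * Z)];
        if (l > 0) { if (seen == 0) seen = l; else if (seen != l) conflict = true; }
      }
      mylab = conflict ? 0 : it.lab;
      lab[i] = mylab;
      if (conflict) continue;  // line voxels do not flood further
    } else {
      mylab = it.lab;
      lab[i] = mylab;
    }
    for (int k = 0; k < 6; ++k) {
      int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      int j = X + nx * (Y + ny * Z);
      if (!done[j] && lab[j] == 0)
        pq.push({ relief[j], counter++, j, mylab });
    }
  }
  return lab;
}

struct GrowItem { double v; long long c; int i; };
struct GrowCmp {  // max-heap on intensity, FIFO on ties
  bool operator()(const GrowItem& a, const GrowItem& b) const {
    if (a.v != b.v) return a.v < b.v;
    return a.c > b.c;
  }
};

// Best-first growth from a seed in order of decreasing intensity, restricted
// to one axial direction (dir = +1: slices z >= z_seed; dir = -1: z <= z_seed).
// Each voxel is enqueued once, by the first expanded neighbour, which becomes
// its path predecessor. Stops at the first accepted voxel |z - z_seed| ==
// depth; returns the predecessor path from that voxel back to the seed
// (1-based linear indices, seed last), the accepted (grown) set, and whether
// the walk was truncated by the volume edge.
// [[Rcpp::export]]
List cpp_grow_path(const NumericVector& intensity, int nx, int ny, int nz,
                   int seed, int depth, int dir) {
  int N = nx * ny * nz;
  int zseed = seed / (nx * ny);
  std::vector<int> pred((size_t)N, -1);
  std::vector<char> queued((size_t)N, 0), done((size_t)N, 0);
  std::priority_queue<GrowItem, std::vector<GrowItem>, GrowCmp> pq;
  long long counter = 0;
  pq.push({ intensity[seed], counter++, seed });
  queued[seed] = 1;
  const int dx[6] = { -1, 1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, -1, 1, 0, 0 };
  const int dz[6] = { 0, 0, 0, 0, -1, 1 };
  int stopv = -1, far = seed, fardist = 0;
  std::vector<int> grown;
  while (!pq.empty()) {
    GrowItem it = pq.top(); pq.pop();
    int i = it.i;
    if (done[i]) continue;
    done[i] = 1;
    grown.push_back(i + 1);
    int z = i / (nx * ny);
    int dist = std::abs(z - zseed);
    if (dist > fardist) { fardist = dist; far = i; }
    if (dist >= depth) { stopv = i; break; }
    int x = i % nx, y = (i / nx) % ny;
    for (int k = 0; k < 6; ++k) {
      int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      if (dir > 0 && Z < zseed) continue;
      if (dir < 0 && Z > zseed) continue;
      int j = X + nx * (Y + ny * Z);
      if (!queued[j]) {
        queued[j] = 1;
        pred[j] = i;
        pq.push({ intensity[j], counter++, j });
      }
    }
  }
  bool truncated = (stopv < 0);
  int v = truncated ? far : stopv;
  std::vector<int> path;
  while (v >= 0) { path.push_back(v + 1); v = pred[v]; }
  return List::create(_["path"] = IntegerVector(path.begin(), path.end()),
                      _["grown"] = IntegerVector(grown.begin(), grown.end()),
                      _["truncated"] = truncated);
}
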