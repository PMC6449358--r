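#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 26-connectivity neighbour offsets for a (X,Y,Z) column-major volume.
static inline void neighbours26(int x, int y, int z, int X, int Y, int Z,
                                std::vector<size_t> &out) {
  out.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int nx = x + dx, ny = y + dy, nz = z + dz;
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z)
          continue;
        out.push_back(nx + (size_t)X * (ny + (size_t)Y * nz));
      }
}

// Connected-component labeling (26-connectivity). Labels are assigned in
// order of the first voxel encountered in column-major scan -> deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  IntegerVector lab(n);
  std::vector<size_t> nb;
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int x = v % X, y = (v / X) % Y, z = v / ((size_t)X * Y);
      neighbours26(x, y, z, X, Y, Z, nb);
      for (size_t u : nb)
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
    }
  }
  return lab;
}

// Strict local maxima within a cubic window of half-width `radius`.
// A voxel is a candidate if no window neighbour exceeds it; plateaus
// (26-connected candidates of equal value) are reduced to the voxel with
// the smallest linear index. Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dims,
                               int radius) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  std::vector<char> cand(n, 0);
  for (size_t i = 0; i < n; ++i) {
    int x = i % X, y = (i / X) % Y, z = i / ((size_t)X * Y);
    double v = vol[i];
    bool ok = true;
    for (int dz = -radius; dz <= radius && ok; ++dz)
      for (int dy = -radius; dy <= radius && ok; ++dy)
        for (int dx = -radius; dx <= radius && ok; ++dx) {
          int nx = x + dx, ny = y + dy, nz = z + dz;
          if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z)
            continue;
          if (vol[nx + (size_t)X * (ny + (size_t)Y * nz)] > v) ok = false;
        }
    cand[i] = ok ? 1 : 0;
  }
  // plateau resolution: keep min linear index per equal-valued component
  std::vector<char> seen(n, 0);
  std::vector<size_t> nb, stack;
  std::vector<int> keep;
  for (size_t i = 0; i < n; ++i) {
    if (!cand[i] || seen[i]) continue;
    double v = vol[i];
    size_t best = i;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      size_t u = stack.back();
      stack.pop_back();
      if (u < best) best = u;
      int x = u % X, y = (u / X) % Y, z = u / ((size_t)X * Y);
      neighbours26(x, y, z, X, Y, Z, nb);
      for (size_t w : nb)
        if (cand[w] && !seen[w] && vol[w] == v) {
          seen[w] = 1;
          stack.push_back(w);
        }
    }
    keep.push_back((int)best + 1);
  }
  std::sort(keep.begin(), keep.end());
  return wrap(keep);
}

// Dilate a set of seed voxels by a Euclidean ball of given radius.
// [[Rcpp::export]]
IntegerVector cpp_dilate_points(IntegerVector dims, IntegerVector seeds,
                                double radius) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerVector out((size_t)X * Y * Z);
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> ball;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          ball.push_back({dx, dy, dz});
  for (int s = 0; s < seeds.size(); ++s) {
    size_t i = (size_t)seeds[s] - 1;
    int x = i % X, y = (i / X) % Y, z = i / ((size_t)X * Y);
    for (auto &d : ball) {
      int nx = x + d[0], ny = y + d[1], nz = z + d[2];
      if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z)
        continue;
      out[nx + (size_t)X * (ny + (size_t)Y * nz)] = 1;
    }
  }
  return out;
}

struct WsNode {
  double elev;
  long long order;
  size_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-controlled watershed by priority flooding: marker voxels are the
// sources; the flood grows into the mask in order of increasing elevation;
// a voxel keeps the label of its first claimant (dams are implicit).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector elev, IntegerVector mask,
                            IntegerVector markers, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  IntegerVector lab(n);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long order = 0;
  for (size_t i = 0; i < n; ++i)
    if (markers[i] != 0 && mask[i] != 0) {
      lab[i] = markers[i];
      pq.push({elev[i], order++, i});
    }
  std::vector<size_t> nb;
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    size_t v = nd.idx;
    int x = v % X, y = (v / X) % Y, z = v / ((size_t)X * Y);
    neighbours26(x, y, z, X, Y, Z, nb);
    for (size_t u : nb)
      if (mask[u] != 0 && lab[u] == 0) {
        lab[u] = lab[v];
        pq.push({elev[u], order++, u});
      }
  }
  return lab;
}
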