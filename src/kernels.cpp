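#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e30;

// 1-D squared distance transform (lower envelope of parabolas),
// sample positions at i*w so anisotropic spacing is handled per axis.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = q * w, s;
    for (;;) {
      double vv = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
      if (s <= z[k] && k > 0) { --k; continue; }
      if (s <= z[k] && k == 0) { s = z[k]; }
      break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * w;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// zero voxel, with per-axis spacing. The caller pads with background
// so the volume border behaves as background.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? BIG : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x (fastest-varying)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// Dijkstra on the 26-connected foreground voxel graph. Edge cost into
// voxel v is (physical step length) / (1 + weight[v])^p, which draws
// minimum-cost routes onto the medial ridge of the weight field.
// src/dst are 0-based linear indices; dst = -1 computes the full field.
// Ties in the priority queue break on the smaller linear index, so the
// result is reproducible bit-for-bit.
// [[Rcpp::export(name = ".dijkstra_grid")]]
List dijkstra_grid(IntegerVector mask, IntegerVector dims, NumericVector spacing,
                   NumericVector weight, double p, int src, int dst,
                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (src < 0 || src >= n || mask[src] == 0)
    stop("source voxel is background or out of range");
  if (dst >= 0 && mask[dst] == 0)
    stop("destination voxel is background");

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  std::vector<double> steps;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nc = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && nc > 1) continue;
        if (connectivity == 18 && nc > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
        double sx = dx * spacing[0], sy = dy * spacing[1], sz = dz * spacing[2];
        steps.push_back(std::sqrt(sx * sx + sy * sy + sz * sz));
      }
  int nn = (int)dxs.size();

  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, -1);
  std::vector<char> done(n, 0);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[src] = 0.0;
  pq.push(Node(0.0, src));

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (dst >= 0 && u == (R_xlen_t)dst) break;
    int uz = (int)(u / ((R_xlen_t)nx * ny));
    int rem = (int)(u % ((R_xlen_t)nx * ny));
    int uy = rem / nx, ux = rem % nx;
    double du = dist[u];
    for (int m = 0; m < nn; ++m) {
      int vx = ux + dxs[m], vy = uy + dys[m], vz = uz + dzs[m];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz) continue;
      R_xlen_t vi = (R_xlen_t)vz * nx * ny + (R_xlen_t)vy * nx + vx;
      if (mask[vi] == 0 || done[vi]) continue;
      double c = du + steps[m] / std::pow(1.0 + weight[vi], p);
      if (c < dist[vi] || (c == dist[vi] && u < pred[vi])) {
        dist[vi] = c;
        pred[vi] = (int)u;
        pq.push(Node(c, vi));
      }
    }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// Connected-component labelling, 26-connected, BFS flood fill.
// Labels are assigned in scan order so the result is deterministic.
// [[Rcpp::export(name = ".components3d")]]
IntegerVector components3d(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t u = stack.back(); stack.pop_back();
      int uz = (int)(u / ((R_xlen_t)nx * ny));
      int rem = (int)(u % ((R_xlen_t)nx * ny));
      int uy = rem / nx, ux = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int vx = ux + dx, vy = uy + dy, vz = uz + dz;
            if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
              continue;
            R_xlen_t vi = (R_xlen_t)vz * nx * ny + (R_xlen_t)vy * nx + vx;
            if (mask[vi] != 0 && lab[vi] == 0) {
              lab[vi] = next;
              stack.push_back(vi);
            }
          }
    }
  }
  return lab;
}

// 2-D 8-connected labelling for cross-section grids.
// [[Rcpp::export(name = ".components2d")]]
IntegerMatrix components2d(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        std::pair<int, int> u = stack.back(); stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int vi = u.first + di, vj = u.second + dj;
            if (vi < 0 || vi >= nr || vj < 0 || vj >= nc) continue;
            if (mask(vi, vj) != 0 && lab(vi, vj) == 0) {
              lab(vi, vj) = next;
              stack.push_back(std::make_pair(vi, vj));
            }
          }
      }
    }
  return lab;
}
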