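// 3D volume primitives for instance post-processing: exact Euclidean
// distance transform (Felzenszwalb's separable lower-envelope method),
// 26-connected component labeling, greyscale reconstruction by dilation
// and Meyer-style priority-flood watershed. Volumes are (Z, Y, X)
// arrays in R's column-major layout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas); cells
// with infinite cost (no source yet) are skipped.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int q0 = -1;
  for (int q = 0; q < n; ++q) if (f[q] < INF) { q0 = q; break; }
  if (q0 < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - (double)v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// Squared Euclidean distance of every nonzero voxel to the nearest zero.
// [[Rcpp::export]]
NumericVector edt_sq_3d_cpp(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  int Z = d[0], Y = d[1], X = d[2];
  size_t n = (size_t)Z * Y * X;
  NumericVector out(n);
  out.attr("dim") = d;
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(Z, std::max(Y, X));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along Z (fastest-varying)
  for (size_t c = 0; c < (size_t)Y * X; ++c) {
    double* col = &out[c * Z];
    bool any = false, inf_all = true;
    for (int i = 0; i < Z; ++i) { f[i] = col[i]; if (col[i] != 0) any = true; if (col[i] != INF) inf_all = false; }
    if (!any || inf_all) continue;
    dt1d(f, dd, v, z, Z);
    for (int i = 0; i < Z; ++i) col[i] = dd[i];
  }
  // pass along Y
  for (int x = 0; x < X; ++x) {
    for (int zz = 0; zz < Z; ++zz) {
      for (int y = 0; y < Y; ++y) f[y] = out[(size_t)x * Z * Y + (size_t)y * Z + zz];
      dt1d(f, dd, v, z, Y);
      for (int y = 0; y < Y; ++y) out[(size_t)x * Z * Y + (size_t)y * Z + zz] = dd[y];
    }
  }
  // pass along X
  for (int y = 0; y < Y; ++y) {
    for (int zz = 0; zz < Z; ++zz) {
      for (int x = 0; x < X; ++x) f[x] = out[(size_t)x * Z * Y + (size_t)y * Z + zz];
      dt1d(f, dd, v, z, X);
      for (int x = 0; x < X; ++x) out[(size_t)x * Z * Y + (size_t)y * Z + zz] = dd[x];
    }
  }
  return out;
}

static void neighbor_offsets(int Z, int Y, int /*X*/, int connectivity,
                             std::vector<long long>& off,
                             std::vector<int>& dz, std::vector<int>& dy,
                             std::vector<int>& dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        off.push_back((long long)c * Z * Y + (long long)b * Z + a);
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// 26-connected (default) component labeling of a binary volume.
// [[Rcpp::export]]
IntegerVector label_cc_3d_cpp(IntegerVector mask, int connectivity = 26) {
  IntegerVector d = mask.attr("dim");
  int Z = d[0], Y = d[1], X = d[2];
  size_t n = (size_t)Z * Y * X;
  IntegerVector lab(n);
  lab.attr("dim") = d;
  std::vector<long long> off; std::vector<int> dz, dy, dx;
  neighbor_offsets(Z, Y, X, connectivity, off, dz, dy, dx);
  int cur = 0;
  std::vector<long long> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.clear(); stack.push_back((long long)i); lab[i] = cur;
    while (!stack.empty()) {
      long long p = stack.back(); stack.pop_back();
      int pz = p % Z, py = (p / Z) % Y, px = p / ((long long)Z * Y);
      for (size_t k = 0; k < off.size(); ++k) {
        int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
        if (qz < 0 || qz >= Z || qy < 0 || qy >= Y || qx < 0 || qx >= X) continue;
        long long q = p + off[k];
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Greyscale reconstruction by dilation of `marker` under `mask`
// (Vincent's FIFO algorithm with raster pre-scans).
// [[Rcpp::export]]
NumericVector grey_reconstruct_cpp(NumericVector marker, NumericVector mask,
                                   int connectivity = 26) {
  IntegerVector d = marker.attr("dim");
  int Z = d[0], Y = d[1], X = d[2];
  size_t n = (size_t)Z * Y * X;
  NumericVector J(n);
  J.attr("dim") = d;
  for (size_t i = 0; i < n; ++i) J[i] = std::min(marker[i], mask[i]);
  std::vector<long long> off; std::vector<int> dz, dy, dx;
  neighbor_offsets(Z, Y, X, connectivity, off, dz, dy, dx);
  size_t m = off.size();
  // forward raster scan
  for (long long p = 0; p < (long long)n; ++p) {
    int pz = p % Z, py = (p / Z) % Y, px = p / ((long long)Z * Y);
    double best = J[p];
    for (size_t k = 0; k < m; ++k) {
      if (off[k] >= 0) continue;
      int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
      if (qz < 0 || qz >= Z || qy < 0 || qy >= Y || qx < 0 || qx >= X) continue;
      best = std::max(best, J[p + off[k]]);
    }
    J[p] = std::min(best, mask[p]);
  }
  // backward raster scan, queueing boundary pixels
  std::queue<long long> fifo;
  for (long long p = (long long)n - 1; p >= 0; --p) {
    int pz = p % Z, py = (p / Z) % Y, px = p / ((long long)Z * Y);
    double best = J[p];
    bool enqueue = false;
    for (size_t k = 0; k < m; ++k) {
      if (off[k] <= 0) continue;
      int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
      if (qz < 0 || qz >= Z || qy < 0 || qy >= Y || qx < 0 || qx >= X) continue;
      long long q = p + off[k];
      best = std::max(best, J[q]);
      if (J[q] < J[p] && J[q] < mask[q]) enqueue = true;
    }
    J[p] = std::min(best, mask[p]);
    if (enqueue) fifo.push(p);
  }
  while (!fifo.empty()) {
    long long p = fifo.front(); fifo.pop();
    int pz = p % Z, py = (p / Z) % Y, px = p / ((long long)Z * Y);
    for (size_t k = 0; k < m; ++k) {
      int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
      if (qz < 0 || qz >= Z || qy < 0 || qy >= Y || qx < 0 || qx >= X) continue;
      long long q = p + off[k];
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

struct WsNode {
  double prio;     // negative distance: lower = flooded later
  long long order; // FIFO tie-break for determinism
  long long idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on prio
    return a.order > b.order;
  }
};

// Priority-flood watershed of -elevation restricted to `mask`, growing
// from labeled seeds; every mask voxel receives the label of the first
// basin that reaches it.
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(NumericVector elevation, IntegerVector seeds,
                                  IntegerVector mask, int connectivity = 26) {
  IntegerVector d = elevation.attr("dim");
  int Z = d[0], Y = d[1], X = d[2];
  size_t n = (size_t)Z * Y * X;
  IntegerVector lab(n);
  lab.attr("dim") = d;
  std::vector<long long> off; std::vector<int> dz, dy, dx;
  neighbor_offsets(Z, Y, X, connectivity, off, dz, dy, dx);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long order = 0;
  for (size_t i = 0; i < n; ++i) {
    if (seeds[i] && mask[i]) {
      lab[i] = seeds[i];
      pq.push({elevation[i], order++, (long long)i});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    long long p = nd.idx;
    int pz = p % Z, py = (p / Z) % Y, px = p / ((long long)Z * Y);
    for (size_t k = 0; k < off.size(); ++k) {
      int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
      if (qz < 0 || qz >= Z || qy < 0 || qy >= Y || qx < 0 || qx >= X) continue;
      long long q = p + off[k];
      if (mask[q] && !lab[q]) {
        lab[q] = lab[p];
        pq.push({elevation[q], order++, q});
      }
    }
  }
  return lab;
}
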