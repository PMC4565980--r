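// Low-level 3-D image primitives used by segmentation and spatial statistics.
// All volumes are passed as flat numeric/logical vectors in R column-major
// order for dim = (nz, ny, nx): linear index i = z + nz*(y + ny*x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Separable Gaussian convolution with reflecting boundaries.
// sigma is per axis in voxel units; an axis with sigma <= 0 is skipped.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dims,
                               NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> cur(vol.begin(), vol.end());
  std::vector<double> nxt(cur.size());

  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (double &w : k) w /= ksum;

    const int n[3] = {nz, ny, nx};
    const int len = n[axis];
    for (int x = 0; x < (axis == 2 ? 1 : nx); ++x)
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
        for (int z = 0; z < (axis == 0 ? 1 : nz); ++z) {
          // convolve the line along `axis` through (z, y, x)
          for (int t = 0; t < len; ++t) {
            double acc = 0.0;
            for (int i = -r; i <= r; ++i) {
              int u = t + i;
              // reflect boundary (half-sample symmetric)
              if (u < 0) u = -u - 1;
              if (u >= len) u = 2 * len - u - 1;
              if (u < 0) u = 0;
              if (u >= len) u = len - 1;
              int zz = (axis == 0) ? u : z;
              int yy = (axis == 1) ? u : y;
              int xx = (axis == 2) ? u : x;
              acc += k[i + r] * cur[idx3(zz, yy, xx, nz, ny)];
            }
            int zz = (axis == 0) ? t : z;
            int yy = (axis == 1) ? t : y;
            int xx = (axis == 2) ? t : x;
            nxt[idx3(zz, yy, xx, nz, ny)] = acc;
          }
        }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// 3-D Laplacian with per-axis physical spacing (nm); replicated boundary.
// [[Rcpp::export]]
NumericVector cpp_laplacian3d(NumericVector vol, IntegerVector dims,
                              NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double wz = 1.0 / (spacing[0] * spacing[0]);
  const double wy = 1.0 / (spacing[1] * spacing[1]);
  const double wx = 1.0 / (spacing[2] * spacing[2]);
  NumericVector out(vol.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const double c = vol[idx3(z, y, x, nz, ny)];
        const double zm = vol[idx3(z > 0 ? z - 1 : 0, y, x, nz, ny)];
        const double zp = vol[idx3(z < nz - 1 ? z + 1 : nz - 1, y, x, nz, ny)];
        const double ym = vol[idx3(z, y > 0 ? y - 1 : 0, x, nz, ny)];
        const double yp = vol[idx3(z, y < ny - 1 ? y + 1 : ny - 1, x, nz, ny)];
        const double xm = vol[idx3(z, y, x > 0 ? x - 1 : 0, nz, ny)];
        const double xp = vol[idx3(z, y, x < nx - 1 ? x + 1 : nx - 1, nz, ny)];
        out[idx3(z, y, x, nz, ny)] =
          wz * (zm + zp - 2 * c) + wy * (ym + yp - 2 * c) + wx * (xm + xp - 2 * c);
      }
  return out;
}

// Connected-component labelling (6 or 26 connectivity), BFS, labels in
// first-encounter order scanning by increasing linear index.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 6) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back((int)start);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int x = cur / (nz * ny);
      const int y = (cur / nz) % ny;
      const int z = cur % nz;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1)
              continue;
            const int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            const int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// 26-neighbourhood local maxima inside `mask`. A voxel qualifies when its
// value exceeds every neighbour, or equals it and has the lower linear
// index (deterministic plateau tie-break).
// [[Rcpp::export]]
LogicalVector cpp_local_max3d(NumericVector vol, LogicalVector mask,
                              IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out(vol.size(), false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const int i = idx3(z, y, x, nz, ny);
        if (!mask[i]) continue;
        const double v = vol[i];
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (dz == 0 && dy == 0 && dx == 0) continue;
              const int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              const int j = idx3(zz, yy, xx, nz, ny);
              if (vol[j] > v || (vol[j] == v && j < i)) ok = false;
            }
        out[i] = ok;
      }
  return out;
}

// Marker-based watershed: grow from seeds over `allowed` voxels in order of
// decreasing intensity (6-connectivity). Ties resolved by insertion order.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector vol, LogicalVector allowed,
                              IntegerVector seeds, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector lab(vol.size(), 0);

  struct Node {
    double v;
    long long order;
    int idx;
    int label;
  };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.v != b.v) return a.v < b.v;     // higher intensity first
      return a.order > b.order;             // then FIFO
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long order = 0;

  for (int s = 0; s < seeds.size(); ++s) {
    const int i = seeds[s] - 1;  // seeds arrive 1-based
    if (i < 0 || i >= (int)vol.size()) stop("seed index out of range");
    pq.push({vol[i], order++, i, s + 1});
  }

  const int off_dz[6] = {-1, 1, 0, 0, 0, 0};
  const int off_dy[6] = {0, 0, -1, 1, 0, 0};
  const int off_dx[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    const Node nd = pq.top();
    pq.pop();
    if (lab[nd.idx]) continue;
    lab[nd.idx] = nd.label;
    const int x = nd.idx / (nz * ny);
    const int y = (nd.idx / nz) % ny;
    const int z = nd.idx % nz;
    for (int k = 0; k < 6; ++k) {
      const int zz = z + off_dz[k], yy = y + off_dy[k], xx = x + off_dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      const int j = idx3(zz, yy, xx, nz, ny);
      if (allowed[j] && !lab[j]) pq.push({vol[j], order++, j, nd.label});
    }
  }
  return lab;
}

// Exact minimum Euclidean distance (nm) from each query point to the set of
// surface voxel centers. Both matrices are n x 3 in (z, y, x) nm.
// [[Rcpp::export]]
NumericVector cpp_min_dist_nm(NumericMatrix pts, NumericMatrix surf) {
  const int n = pts.nrow(), m = surf.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double pz = pts(i, 0), py = pts(i, 1), px = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dz = pz - surf(j, 0);
      const double dy = py - surf(j, 1);
      const double dx = px - surf(j, 2);
      const double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
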