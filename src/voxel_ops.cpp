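#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids are passed as flat vectors in R's column-major layout:
// linear index = i + nx*(j + ny*k), 0-based.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Connected-component labelling of a logical mask, 26-connectivity.
// Components are numbered 1,2,... in raster-scan order of their first voxel,
// so the component containing the lowest linear index has the lowest label.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask,
                                   const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0]) continue;
    ++next;
    lab[v0] = next;
    stack.push_back(v0);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int w = lin(ii, jj, kk, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on samples at
// positions x_i = i*h; f holds squared distances, INF where no source yet.
static void dt1d(std::vector<double>& f, double h, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; z[k] = -INF; z[k + 1] = INF; continue; }
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = (f[v[k]] == INF) ? INF : dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance (mm) from each in-mask voxel to the nearest voxel
// outside the mask, under anisotropic spacing. Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt(const LogicalVector& mask, const IntegerVector& dims,
                      const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (int v = 0; v < n; ++v) g[v] = mask[v] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> vv(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      f.assign(nx, 0.0);
      for (int i = 0; i < nx; ++i) f[i] = g[lin(i, j, k, nx, ny)];
      dt1d(f, spacing[0], d, vv, z);
      for (int i = 0; i < nx; ++i) g[lin(i, j, k, nx, ny)] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      f.assign(ny, 0.0);
      for (int j = 0; j < ny; ++j) f[j] = g[lin(i, j, k, nx, ny)];
      dt1d(f, spacing[1], d, vv, z);
      for (int j = 0; j < ny; ++j) g[lin(i, j, k, nx, ny)] = f[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      f.assign(nz, 0.0);
      for (int k = 0; k < nz; ++k) f[k] = g[lin(i, j, k, nx, ny)];
      dt1d(f, spacing[2], d, vv, z);
      for (int k = 0; k < nz; ++k) g[lin(i, j, k, nx, ny)] = f[k];
    }

  NumericVector out(n);
  for (int v = 0; v < n; ++v)
    out[v] = std::isfinite(g[v]) ? std::sqrt(g[v]) : 0.0;
  return out;
}

// Dijkstra over the 26-connected voxel graph restricted to `mask`.
// Edge cost = world step length * (1 + alpha * (1 - dt_target/dt_max)^2),
// which keeps shortest paths on the medial (high-distance-transform) ridge.
// Returns the voxel farthest (in penalized distance) from `source`, and the
// 0-based linear-index path source -> farthest.
// [[Rcpp::export]]
List cpp_penalized_geodesic(const LogicalVector& mask, const NumericVector& dt,
                            const IntegerVector& dims,
                            const NumericVector& spacing,
                            int source, double alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  double dtmax = 0.0;
  for (int v = 0; v < n; ++v)
    if (mask[v] && dt[v] > dtmax) dtmax = dt[v];
  if (dtmax <= 0) dtmax = 1.0;

  std::vector<double> dist(n, INF);
  std::vector<int> pred(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[source] = 0.0;
  pq.push(QE(0.0, source));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > dist[v]) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int w = lin(ii, jj, kk, nx, ny);
          if (!mask[w]) continue;
          double sx = di * spacing[0], sy = dj * spacing[1],
                 sz = dk * spacing[2];
          double step = std::sqrt(sx * sx + sy * sy + sz * sz);
          double med = 1.0 - dt[w] / dtmax;
          double cost = step * (1.0 + alpha * med * med);
          double nd = dist[v] + cost;
          if (nd < dist[w]) {
            dist[w] = nd;
            pred[w] = v;
            pq.push(QE(nd, w));
          }
        }
  }
  int far = source;
  double dmax = 0.0;
  for (int v = 0; v < n; ++v)
    if (mask[v] && std::isfinite(dist[v]) && dist[v] > dmax) {
      dmax = dist[v];
      far = v;
    }
  std::vector<int> path;
  for (int v = far; v != -1; v = pred[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  return List::create(_["farthest"] = far,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
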