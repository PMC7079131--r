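// Grid-indexed planar point queries used by the localization analyses:
// first-nearest-neighbor distances and density-reachability (DBSCAN)
// clustering.  A uniform bucket grid is sufficient here because
// localization fields are bounded and eps / typical NN scales are small
// relative to the field.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

namespace {

struct PointGrid {
  double cell;
  double x0, y0;
  int nx, ny;
  std::vector<std::vector<int>> bucket;

  PointGrid(const NumericVector& x, const NumericVector& y, double cell_hint) {
    const int n = x.size();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    const double ext = std::max(xmax - xmin, ymax - ymin);
    // cap the grid at 2048 cells per axis to bound memory
    cell = std::max(cell_hint, ext / 2048.0);
    if (!(cell > 0.0)) cell = 1.0;
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
    bucket.assign((size_t)nx * (size_t)ny, std::vector<int>());
    for (int i = 0; i < n; ++i) bucket[idx(cx(x[i]), cy(y[i]))].push_back(i);
  }

  inline int cx(double v) const {
    int c = (int)std::floor((v - x0) / cell);
    if (c < 0) c = 0;
    if (c >= nx) c = nx - 1;
    return c;
  }
  inline int cy(double v) const {
    int c = (int)std::floor((v - y0) / cell);
    if (c < 0) c = 0;
    if (c >= ny) c = ny - 1;
    return c;
  }
  inline size_t idx(int cx_, int cy_) const {
    return (size_t)cy_ * (size_t)nx + (size_t)cx_;
  }
};

inline double sqdist(double ax, double ay, double bx, double by) {
  const double dx = ax - bx, dy = ay - by;
  return dx * dx + dy * dy;
}

} // namespace

// [[Rcpp::export(name = ".nn_dist_grid")]]
NumericVector nn_dist_grid(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  if (n < 2) stop("need at least 2 points");
  // aim for O(1) points per cell
  double xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y);
  double ext = std::max(xmax - xmin, ymax - ymin);
  double hint = ext > 0 ? ext / std::max(4.0, std::sqrt((double)n)) : 1.0;
  PointGrid g(x, y, hint);

  const int max_ring = std::max(g.nx, g.ny);
  for (int i = 0; i < n; ++i) {
    const int ci = g.cx(x[i]), cj = g.cy(y[i]);
    double best = R_PosInf;
    for (int d = 0; d <= max_ring; ++d) {
      // points not yet scanned lie in cell-ring > d, hence at distance
      // >= (d)*cell - (in-cell offset); conservative bound (d-1)*cell
      if (d > 0 && best <= (double)(d - 1) * g.cell * (double)(d - 1) * g.cell)
        break;
      const int xlo = std::max(0, ci - d), xhi = std::min(g.nx - 1, ci + d);
      const int ylo = std::max(0, cj - d), yhi = std::min(g.ny - 1, cj + d);
      for (int cyy = ylo; cyy <= yhi; ++cyy) {
        for (int cxx = xlo; cxx <= xhi; ++cxx) {
          // only the ring at Chebyshev distance d
          if (std::max(std::abs(cxx - ci), std::abs(cyy - cj)) != d) continue;
          const std::vector<int>& b = g.bucket[g.idx(cxx, cyy)];
          for (size_t k = 0; k < b.size(); ++k) {
            const int j = b[k];
            if (j == i) continue;
            const double d2 = sqdist(x[i], y[i], x[j], y[j]);
            if (d2 < best) best = d2;
          }
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export(name = ".dbscan_grid")]]
IntegerVector dbscan_grid(NumericVector x, NumericVector y, double eps,
                          int min_pts) {
  const int n = x.size();
  IntegerVector cluster(n, 0); // 0 = noise / unassigned
  if (n == 0) return cluster;
  if (eps <= 0) stop("eps must be > 0");
  if (min_pts < 2) stop("min_pts must be >= 2");

  PointGrid g(x, y, eps);
  const int reach = std::max(1, (int)std::ceil(eps / g.cell));
  const double eps2 = eps * eps;

  std::vector<int> neigh;
  neigh.reserve(64);
  auto region_query = [&](int i) {
    neigh.clear();
    const int ci = g.cx(x[i]), cj = g.cy(y[i]);
    const int xlo = std::max(0, ci - reach), xhi = std::min(g.nx - 1, ci + reach);
    const int ylo = std::max(0, cj - reach), yhi = std::min(g.ny - 1, cj + reach);
    for (int cyy = ylo; cyy <= yhi; ++cyy)
      for (int cxx = xlo; cxx <= xhi; ++cxx) {
        const std::vector<int>& b = g.bucket[g.idx(cxx, cyy)];
        for (size_t k = 0; k < b.size(); ++k) {
          const int j = b[k];
          if (sqdist(x[i], y[i], x[j], y[j]) <= eps2) neigh.push_back(j);
        }
      }
  };

  std::vector<char> visited(n, 0);
  int next_id = 0;
  std::queue<int> todo;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    region_query(i);
    if ((int)neigh.size() < min_pts) continue; // noise (may become border later)
    ++next_id;
    cluster[i] = next_id;
    for (size_t k = 0; k < neigh.size(); ++k) todo.push(neigh[k]);
    while (!todo.empty()) {
      const int j = todo.front();
      todo.pop();
      if (cluster[j] == 0) cluster[j] = next_id; // border or core member
      if (visited[j]) continue;
      visited[j] = 1;
      region_query(j);
      if ((int)neigh.size() >= min_pts) {
        for (size_t k = 0; k < neigh.size(); ++k) {
          const int m = neigh[k];
          if (!visited[m] || cluster[m] == 0) todo.push(m);
        }
      }
    }
  }
  return cluster;
}
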