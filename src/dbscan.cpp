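#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Spatial hash over cells of side eps so a radius query only visits the
// 3^d neighbouring cells.
static inline std::int64_t cell_key(int cx, int cy, int cz) {
  // pack three 21-bit signed cell coordinates
  const std::int64_t B = 1 << 20;
  return ((std::int64_t)(cx + B) << 42) | ((std::int64_t)(cy + B) << 21) |
         (std::int64_t)(cz + B);
}

// DBSCAN over 2D/3D point coordinates. eps: neighbourhood radius; min_pts:
// minimum neighbourhood size (the point itself counts) for a core point.
// Returns integer labels: 0 = noise, 1..k = clusters.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow(), d = pts.ncol();
  if (d != 2 && d != 3) stop("points must be 2- or 3-dimensional");
  if (eps <= 0) stop("eps must be positive");
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  std::unordered_map<std::int64_t, std::vector<int> > grid;
  grid.reserve((size_t)n);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(pts(i, 0) / eps);
    cy[i] = (int)std::floor(pts(i, 1) / eps);
    cz[i] = d == 3 ? (int)std::floor(pts(i, 2) / eps) : 0;
    grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }

  double eps2 = eps * eps;
  std::vector<int> neigh;
  neigh.reserve(256);
  auto region_query = [&](int i) {
    neigh.clear();
    for (int ax = -1; ax <= 1; ++ax)
      for (int ay = -1; ay <= 1; ++ay)
        for (int az = (d == 3 ? -1 : 0); az <= (d == 3 ? 1 : 0); ++az) {
          auto it = grid.find(cell_key(cx[i] + ax, cy[i] + ay, cz[i] + az));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double s = 0;
            for (int k = 0; k < d; ++k) {
              double diff = pts(i, k) - pts(j, k);
              s += diff * diff;
            }
            if (s <= eps2) neigh.push_back(j);
          }
        }
  };

  std::vector<char> core(n, 0), processed(n, 0);
  for (int i = 0; i < n; ++i) {
    region_query(i);
    core[i] = (int)neigh.size() >= min_pts;
  }

  int next_label = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (processed[i] || !core[i]) continue;
    ++next_label;
    stack.clear();
    stack.push_back(i);
    processed[i] = 1;
    labels[i] = next_label;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      if (!core[p]) continue;
      region_query(p);
      for (size_t k = 0; k < neigh.size(); ++k) {
        int q = neigh[k];
        if (labels[q] == 0) labels[q] = next_label;
        if (!processed[q]) {
          processed[q] = 1;
          if (core[q]) stack.push_back(q);
        }
      }
    }
  }
  return labels;
}
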