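#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D topological thinning to a voxel curve skeleton: iterative removal of
// simple border points, preserving curve endpoints, in six directional
// sub-iterations per pass. A voxel is simple (Malandain & Bertrand
// characterisation) when its foreground 26-neighbours form exactly one
// 26-connected component and the 6-adjacent background within the
// 18-neighbourhood forms exactly one 6-connected component.

static int nbr26_idx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1); // 0..26, centre = 13
}

// count 26-connected components of foreground among the 26 neighbours
static int fg_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    // BFS
    int stack[27], top = 0;
    stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int p = stack[--top];
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int qx = px + dx, qy = py + dy, qz = pz + dz;
            if (qx < 0 || qx > 2 || qy < 0 || qy > 2 || qz < 0 || qz > 2)
              continue;
            int q = qx + 3 * qy + 9 * qz;
            if (q == 13 || q == p || seen[q] || !nb[q]) continue;
            seen[q] = true;
            stack[top++] = q;
          }
    }
  }
  return comps;
}

// count 6-connected components of background in the 18-neighbourhood that
// are 6-adjacent to the centre
static int bg_components(const bool nb[27]) {
  // 18-neighbourhood: |dx|+|dy|+|dz| <= 2 excluding centre and corners
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = nbr26_idx(dx, dy, dz);
        int m = (dx != 0) + (dy != 0) + (dz != 0);
        in18[s] = (m >= 1 && m <= 2);
      }
  bool seen[27] = {false};
  int comps = 0;
  const int face[6] = {nbr26_idx(-1, 0, 0), nbr26_idx(1, 0, 0),
                       nbr26_idx(0, -1, 0), nbr26_idx(0, 1, 0),
                       nbr26_idx(0, 0, -1), nbr26_idx(0, 0, 1)};
  for (int fi = 0; fi < 6; ++fi) {
    int s = face[fi];
    if (nb[s] || seen[s]) continue; // want background seeds at face positions
    ++comps;
    int stack[27], top = 0;
    stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int p = stack[--top];
      int px = p % 3 - 1, py = (p / 3) % 3 - 1, pz = p / 9 - 1;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int qx = px + d6[k][0], qy = py + d6[k][1], qz = pz + d6[k][2];
        if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1)
          continue;
        int q = nbr26_idx(qx, qy, qz);
        if (q == 13 || seen[q] || nb[q] || !in18[q]) continue;
        seen[q] = true;
        stack[top++] = q;
      }
    }
  }
  return comps;
}

class Vol {
public:
  std::vector<char>& v;
  int nx, ny, nz;
  Vol(std::vector<char>& v_, int nx_, int ny_, int nz_)
    : v(v_), nx(nx_), ny(ny_), nz(nz_) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return v[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] != 0;
  }
  void neighbourhood(int x, int y, int z, bool nb[27]) const {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[nbr26_idx(dx, dy, dz)] = at(x + dx, y + dy, z + dz);
  }
  int n_fg_neighbours(int x, int y, int z) const {
    int n = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (at(x + dx, y + dy, z + dz)) ++n;
        }
    return n;
  }
};

static bool is_simple(const Vol& vol, int x, int y, int z) {
  bool nb[27];
  vol.neighbourhood(x, y, z, nb);
  return fg_components(nb) == 1 && bg_components(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector volume, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((size_t)volume.size() != (size_t)nx * ny * nz)
    stop("volume length does not match dims");
  std::vector<char> v((size_t)nx * ny * nz);
  for (size_t i = 0; i < v.size(); ++i) v[i] = volume[i] ? 1 : 0;
  Vol vol(v, nx, ny, nz);

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  std::vector<int> fg; // linear indices of foreground voxels
  fg.reserve(v.size() / 8);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (vol.at(x, y, z)) fg.push_back(x + nx * (y + ny * z));

  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int di = 0; di < 6; ++di) {
      cand.clear();
      for (size_t i = 0; i < fg.size(); ++i) {
        int p = fg[i];
        int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
        if (!vol.at(x, y, z)) continue;
        // border in this direction: face neighbour is background
        if (vol.at(x + dirs[di][0], y + dirs[di][1], z + dirs[di][2]))
          continue;
        int nfg = vol.n_fg_neighbours(x, y, z);
        if (nfg <= 1) continue; // endpoint (or isolated): preserve
        if (is_simple(vol, x, y, z)) cand.push_back(p);
      }
      // sequential re-check: deleting one candidate can make another
      // non-simple, so verify against the current volume before removal
      for (size_t i = 0; i < cand.size(); ++i) {
        int p = cand[i];
        int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
        if (vol.n_fg_neighbours(x, y, z) <= 1) continue;
        if (is_simple(vol, x, y, z)) {
          v[(size_t)p] = 0;
          changed = true;
        }
      }
    }
    // compact the foreground list
    size_t w = 0;
    for (size_t i = 0; i < fg.size(); ++i)
      if (v[(size_t)fg[i]]) fg[w++] = fg[i];
    fg.resize(w);
  }

  LogicalVector out(volume.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
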