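#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Neighbour offsets for 2D connectivity. conn = 4 or 8.
static inline int n_offsets(int conn) { return conn; }

static void fill_offsets(int conn, int nr, int dr[8], int dc[8]) {
  // order: N, S, W, E, then diagonals
  int r4[4] = {-1, 1, 0, 0};
  int c4[4] = {0, 0, -1, 1};
  int r8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int c8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  (void)nr;
  for (int i = 0; i < conn; ++i) {
    dr[i] = (conn == 4) ? r4[i] : r8[i];
    dc[i] = (conn == 4) ? c4[i] : c8[i];
  }
}

// Grayscale morphological reconstruction by dilation of `marker` under `mask`
// (marker <= mask everywhere), using the hybrid raster-scan + FIFO queue
// algorithm. Returns the reconstructed image.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask,
                                     int conn = 8) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  NumericMatrix J(clone(marker));
  // clamp marker under mask
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) J[i] = mask[i];

  int dr[8], dc[8];
  fill_offsets(conn, nr, dr, dc);
  int half = conn / 2 + (conn == 8 ? 2 : 0); // 4-conn: {N,W}; 8-conn handled below

  // raster scans run column-major (r fastest). Forward-pass neighbours must
  // be the already-visited ones: N, W, NW, SW for 8-conn; N, W for 4-conn.
  // The backward pass uses their reflections.
  int rr_f[4], cc_f[4], nf = 0;
  int rr_b[4], cc_b[4], nb = 0;
  if (conn == 4) {
    rr_f[0] = -1; cc_f[0] = 0; rr_f[1] = 0; cc_f[1] = -1; nf = 2;
    rr_b[0] = 1;  cc_b[0] = 0; rr_b[1] = 0; cc_b[1] = 1;  nb = 2;
  } else {
    int rf[4] = {-1, 0, -1, 1}, cf[4] = {0, -1, -1, -1};
    int rb[4] = {1, 0, 1, -1},  cb[4] = {0, 1, 1, 1};
    for (int i = 0; i < 4; ++i) {
      rr_f[i] = rf[i]; cc_f[i] = cf[i];
      rr_b[i] = rb[i]; cc_b[i] = cb[i];
    }
    nf = nb = 4;
  }
  (void)half;

  // forward pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < nf; ++k) {
        int r2 = r + rr_f[k], c2 = c + cc_f[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) > v) v = J(r2, c2);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }

  std::queue<int> fifo;
  // backward pass + queue seeding
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < nb; ++k) {
        int r2 = r + rr_b[k], c2 = c + cc_b[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) > v) v = J(r2, c2);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      for (int k = 0; k < nb; ++k) {
        int r2 = r + rr_b[k], c2 = c + cc_b[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) < J(r, c) && J(r2, c2) < mask(r2, c2)) {
          fifo.push(r + nr * c);
          break;
        }
      }
    }

  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < conn; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (J(r2, c2) < J(r, c) && mask(r2, c2) != J(r2, c2)) {
        double v = J(r, c) < mask(r2, c2) ? J(r, c) : mask(r2, c2);
        if (v > J(r2, c2)) {
          J(r2, c2) = v;
          fifo.push(r2 + nr * c2);
        }
      }
    }
  }
  return J;
}

// Regional maxima: connected plateaus (equal grey value, given connectivity)
// with no strictly brighter neighbour. Returns a logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img, int conn = 8) {
  int nr = img.nrow(), nc = img.ncol();
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  int dr[8], dc[8];
  fill_offsets(conn, nr, dr, dc);
  LogicalMatrix out(nr, nc);
  std::vector<char> visited((size_t)nr * nc, 0);
  std::vector<int> plateau;
  std::queue<int> q;

  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      int p0 = r0 + nr * c0;
      if (visited[p0]) continue;
      double v = img(r0, c0);
      bool is_max = true;
      plateau.clear();
      q.push(p0);
      visited[p0] = 1;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        plateau.push_back(p);
        int r = p % nr, c = p / nr;
        for (int k = 0; k < conn; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          double v2 = img(r2, c2);
          if (v2 > v) { is_max = false; continue; }
          if (v2 == v) {
            int p2 = r2 + nr * c2;
            if (!visited[p2]) { visited[p2] = 1; q.push(p2); }
          }
        }
      }
      if (is_max)
        for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = true;
    }
  return out;
}

struct WsNode {
  double prio;
  int label;
  std::int64_t seq;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    // ties resolve by insertion order, so fronts at the same level advance
    // together instead of one basin sweeping whole tied shells
    return a.seq > b.seq;
  }
};

// Marker-controlled watershed by priority flooding of `priority` (lower
// values flooded first) restricted to `mask`. `markers` carries positive
// integer labels at seed pixels; each basin grows from its marker. Pixels on
// inter-basin ridges go to the basin that reaches them at the lowest
// priority, ties broken by insertion order so tied fronts advance evenly and
// the result is deterministic. Markers outside the mask are ignored; the
// number ignored is returned as attribute "n_ignored_markers".
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask, int conn = 8) {
  int nr = priority.nrow(), nc = priority.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("priority, markers and mask must have identical dimensions");
  int dr[8], dc[8];
  fill_offsets(conn, nr, dr, dc);

  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  std::int64_t seq = 0;
  int n_ignored = 0;

  for (int i = 0; i < nr * nc; ++i) {
    if (markers[i] > 0) {
      if (mask[i]) {
        WsNode nd; nd.prio = priority[i]; nd.label = markers[i];
        nd.seq = seq++; nd.idx = i;
        pq.push(nd);
      } else {
        ++n_ignored;
      }
    }
  }

  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    if (lab[nd.idx] != 0) continue;
    lab[nd.idx] = nd.label;
    int r = nd.idx % nr, c = nd.idx / nr;
    for (int k = 0; k < conn; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int p2 = r2 + nr * c2;
      if (!mask[p2] || lab[p2] != 0) continue;
      WsNode nx; nx.prio = priority(r2, c2); nx.label = nd.label;
      nx.seq = seq++; nx.idx = p2;
      pq.push(nx);
    }
  }
  lab.attr("n_ignored_markers") = n_ignored;
  return lab;
}
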