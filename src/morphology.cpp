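#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 8-connected neighbourhood offsets
static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY4[4] = {-1, 0, 0, 1};
static const int DX4[4] = {-1, 1, 0, 0};

// Label connected components of a binary image. Components are numbered
// 1..K in raster order of their first-encountered pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix fg, int connectivity = 8) {
  int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dy = (connectivity == 8) ? DY8 : DY4;
  const int *dx = (connectivity == 8) ? DX8 : DX4;
  int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      if (!fg(y, x) || lab(y, x)) continue;
      ++next;
      stack.clear();
      stack.push_back(y + x * nr);
      lab(y, x) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cy = idx % nr, cx = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
          if (fg(ny, nx) && !lab(ny, nx)) {
            lab(ny, nx) = next;
            stack.push_back(ny + nx * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background not reachable (4-connectivity) from the
// image border becomes foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  LogicalMatrix reach(nr, nc);
  std::vector<int> stack;
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      if ((y == 0 || y == nr - 1 || x == 0 || x == nc - 1) &&
          !fg(y, x) && !reach(y, x)) {
        reach(y, x) = true;
        stack.push_back(y + x * nr);
      }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int cy = idx % nr, cx = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ny = cy + DY4[k], nx = cx + DX4[k];
      if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
      if (!fg(ny, nx) && !reach(ny, nx)) {
        reach(ny, nx) = true;
        stack.push_back(ny + nx * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = fg[i] || !reach[i];
  return out;
}

// Two-pass chamfer (3,4)/3 distance transform: distance of each foreground
// pixel to the nearest background pixel, in approximate pixel units.
// [[Rcpp::export(name = ".chamfer_dist")]]
NumericMatrix chamfer_dist(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  const double BIG = 1e30, A = 3.0, D = 4.0;
  NumericMatrix d(nr, nc);
  for (int i = 0; i < nr * nc; ++i) d[i] = fg[i] ? BIG : 0.0;
  // forward: N, W, NW, NE
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double v = d(y, x);
      if (v == 0.0) continue;
      if (y > 0) v = std::min(v, d(y - 1, x) + A);
      if (x > 0) v = std::min(v, d(y, x - 1) + A);
      if (y > 0 && x > 0) v = std::min(v, d(y - 1, x - 1) + D);
      if (y < nr - 1 && x > 0) v = std::min(v, d(y + 1, x - 1) + D);
      d(y, x) = v;
    }
  // backward: S, E, SE, SW
  for (int x = nc - 1; x >= 0; --x)
    for (int y = nr - 1; y >= 0; --y) {
      double v = d(y, x);
      if (v == 0.0) continue;
      if (y < nr - 1) v = std::min(v, d(y + 1, x) + A);
      if (x < nc - 1) v = std::min(v, d(y, x + 1) + A);
      if (y < nr - 1 && x < nc - 1) v = std::min(v, d(y + 1, x + 1) + D);
      if (y > 0 && x < nc - 1) v = std::min(v, d(y - 1, x + 1) + D);
      d(y, x) = v;
    }
  for (int i = 0; i < nr * nc; ++i) if (d[i] > 0) d[i] /= A;
  return d;
}

// Peak picking on a distance map: candidates are pixels of height >=
// min_height that attain the maximum of their (min_distance/2)-radius
// window; candidates sorted by decreasing height (raster order breaks
// ties) are then greedily suppressed so no two kept peaks lie within
// min_distance (Euclidean). Returns a K x 2 matrix of 1-based (row, col)
// peak coordinates.
// [[Rcpp::export(name = ".find_peaks")]]
IntegerMatrix find_peaks(NumericMatrix dist, LogicalMatrix mask,
                         double min_distance, double min_height = 2.0) {
  int nr = dist.nrow(), nc = dist.ncol();
  int wr = std::max(1, (int)(min_distance / 2));
  std::vector<int> idx;
  for (int i = 0; i < nr * nc; ++i) {
    if (!mask[i] || dist[i] < min_height) continue;
    int cy = i % nr, cx = i / nr;
    bool is_max = true;
    for (int dy = -wr; dy <= wr && is_max; ++dy)
      for (int dx = -wr; dx <= wr; ++dx) {
        int ny = cy + dy, nx = cx + dx;
        if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
        if (dist(ny, nx) > dist[i]) { is_max = false; break; }
      }
    if (is_max) idx.push_back(i);
  }
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return dist[a] > dist[b]; });
  std::vector<int> py, px;
  double md2 = min_distance * min_distance;
  for (int i : idx) {
    int cy = i % nr, cx = i / nr;
    bool ok = true;
    for (size_t k = 0; k < py.size(); ++k) {
      double dy = cy - py[k], dx = cx - px[k];
      if (dy * dy + dx * dx < md2) { ok = false; break; }
    }
    if (ok) { py.push_back(cy); px.push_back(cx); }
  }
  IntegerMatrix out(py.size(), 2);
  for (size_t k = 0; k < py.size(); ++k) {
    out(k, 0) = py[k] + 1;
    out(k, 1) = px[k] + 1;
  }
  return out;
}

struct WsNode {
  double h;     // elevation = -distance (flood lowest first)
  long order;   // FIFO tie-break
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.h != b.h) return a.h > b.h;   // min-heap on elevation
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding on -dist restricted to mask.
// seeds: integer matrix, 0 = unseeded, k > 0 = region label.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerMatrix watershed_seeded(NumericMatrix dist, IntegerMatrix seeds,
                               LogicalMatrix mask) {
  int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int i = 0; i < nr * nc; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({-dist[i], order++, i});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int cy = nd.idx % nr, cx = nd.idx / nr;
    int l = lab[nd.idx];
    for (int k = 0; k < 8; ++k) {
      int ny = cy + DY8[k], nx = cx + DX8[k];
      if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
      int j = ny + nx * nr;
      if (!mask[j] || lab[j]) continue;
      lab[j] = l;
      pq.push({-dist[j], order++, j});
    }
  }
  return lab;
}
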