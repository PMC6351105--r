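#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Connected-component labeling of a binary image.
// Labels are assigned in raster-scan order (row by row, left to right) of
// each component's first pixel, so the labeling is deterministic.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int *dy = (connectivity == 4) ? dy4 : dy8;
  const int *dx = (connectivity == 4) ? dx4 : dx8;
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int yy = p.first + dy[k], xx = p.second + dx[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            q.push(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return lab;
}

static std::vector<std::pair<int, int> > bresenham(int y0, int x0, int y1,
                                                   int x1) {
  // 8-connected digital straight segment between two pixels (inclusive)
  std::vector<std::pair<int, int> > px;
  int dy = std::abs(y1 - y0), dx = std::abs(x1 - x0);
  int sy = (y0 < y1) ? 1 : -1, sx = (x0 < x1) ? 1 : -1;
  int err = dx - dy, y = y0, x = x0;
  while (true) {
    px.push_back(std::make_pair(y, x));
    if (y == y1 && x == x1) break;
    int e2 = 2 * err;
    if (e2 > -dy) { err -= dy; x += sx; }
    if (e2 < dx)  { err += dx; y += sy; }
  }
  return px;
}

// [[Rcpp::export]]
IntegerMatrix bresenham_cpp(int y0, int x0, int y1, int x1) {
  std::vector<std::pair<int, int> > px = bresenham(y0 - 1, x0 - 1, y1 - 1,
                                                   x1 - 1);
  IntegerMatrix out(px.size(), 2);
  for (size_t i = 0; i < px.size(); ++i) {
    out(i, 0) = px[i].first + 1;
    out(i, 1) = px[i].second + 1;
  }
  return out;
}

struct Cand {
  long long len2;
  int ay, ax, by, bx;
};

static bool cand_less(const Cand &a, const Cand &b) {
  if (a.len2 != b.len2) return a.len2 < b.len2;
  if (a.ay != b.ay) return a.ay < b.ay;
  if (a.ax != b.ax) return a.ax < b.ax;
  if (a.by != b.by) return a.by < b.by;
  return a.bx < b.bx;
}

// component count and smallest component size of mask minus `removed`
static void components_after(const LogicalMatrix &mask,
                             const std::vector<bool> &removed,
                             int connectivity, int *ncomp_out,
                             int *minsize_out) {
  const int ny = mask.nrow(), nx = mask.ncol();
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int *dy = (connectivity == 4) ? dy4 : dy8;
  const int *dx = (connectivity == 4) ? dx4 : dx8;
  const int nn = (connectivity == 4) ? 4 : 8;
  std::vector<bool> seen((size_t)ny * nx, false);
  int ncomp = 0, minsize = 0;
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      size_t id = (size_t)x * ny + y;
      if (!mask(y, x) || removed[id] || seen[id]) continue;
      ++ncomp;
      if (ncomp > 2) { *ncomp_out = ncomp; *minsize_out = 0; return; }
      int size = 1;
      seen[id] = true;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int yy = p.first + dy[k], xx = p.second + dx[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          size_t jd = (size_t)xx * ny + yy;
          if (mask(yy, xx) && !removed[jd] && !seen[jd]) {
            seen[jd] = true;
            ++size;
            q.push(std::make_pair(yy, xx));
          }
        }
      }
      if (ncomp == 1 || size < minsize) minsize = size;
    }
  }
  *ncomp_out = ncomp;
  *minsize_out = minsize;
}

// Shortest bisecting chord of a 2D object. `pts` are boundary pixels
// (1-based (y, x) rows) and `memb` their centroid-quadrant memberships
// (n x 4 logical; membership is band-inclusive near the axes). A pair of
// boundary pixels is a candidate when the two pixels are not confined to
// a single common quadrant, i.e. the chord crosses a centroid axis. A
// candidate is valid when its 8-connected rasterization lies entirely
// inside `mask` and removing its pixels bisects the object into exactly
// two components, each of at least `min_child` pixels. Candidates are
// scanned in order of (squared length, endpoint raster order) — ties
// break deterministically — and at most `max_checks` inside-valid
// candidates are component-checked before giving up. Returns a list with
// found flag, endpoints, chord length, and chord pixels.
// [[Rcpp::export]]
List shortest_cut_cpp(LogicalMatrix mask, IntegerMatrix pts,
                      LogicalMatrix memb, int connectivity = 8,
                      int min_child = 6, int max_checks = 512) {
  const int ny = mask.nrow(), nx = mask.ncol();
  const int n = pts.nrow();
  std::vector<unsigned char> sig(n);
  for (int i = 0; i < n; ++i) {
    unsigned char s = 0;
    for (int k = 0; k < 4; ++k) if (memb(i, k)) s |= (1 << k);
    sig[i] = s;
  }
  std::vector<Cand> cands;
  cands.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      unsigned char u = sig[i] | sig[j];
      if (u == 1 || u == 2 || u == 4 || u == 8) continue;  // one quadrant
      Cand c;
      c.ay = pts(i, 0) - 1; c.ax = pts(i, 1) - 1;
      c.by = pts(j, 0) - 1; c.bx = pts(j, 1) - 1;
      long long ddy = c.ay - c.by, ddx = c.ax - c.bx;
      c.len2 = ddy * ddy + ddx * ddx;
      if (c.len2 == 0) continue;
      // orient each pair so the raster-smaller endpoint comes first
      if (c.by < c.ay || (c.by == c.ay && c.bx < c.ax)) {
        std::swap(c.ay, c.by);
        std::swap(c.ax, c.bx);
      }
      cands.push_back(c);
    }
  }
  std::sort(cands.begin(), cands.end(), cand_less);
  std::vector<bool> removed((size_t)ny * nx, false);
  int checks = 0;
  for (size_t k = 0; k < cands.size(); ++k) {
    const Cand &c = cands[k];
    std::vector<std::pair<int, int> > px =
        bresenham(c.ay, c.ax, c.by, c.bx);
    bool ok = true;
    for (size_t m = 0; m < px.size(); ++m) {
      int yy = px[m].first, xx = px[m].second;
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || !mask(yy, xx)) {
        ok = false;
        break;
      }
    }
    if (!ok) continue;
    if (++checks > max_checks) break;
    for (size_t m = 0; m < px.size(); ++m)
      removed[(size_t)px[m].second * ny + px[m].first] = true;
    int ncomp = 0, minsize = 0;
    components_after(mask, removed, connectivity, &ncomp, &minsize);
    for (size_t m = 0; m < px.size(); ++m)
      removed[(size_t)px[m].second * ny + px[m].first] = false;
    if (ncomp != 2 || minsize < min_child) continue;
    IntegerMatrix cut(px.size(), 2);
    for (size_t m = 0; m < px.size(); ++m) {
      cut(m, 0) = px[m].first + 1;
      cut(m, 1) = px[m].second + 1;
    }
    return List::create(_["found"] = true, _["y0"] = c.ay + 1,
                        _["x0"] = c.ax + 1, _["y1"] = c.by + 1,
                        _["x1"] = c.bx + 1,
                        _["length"] = std::sqrt((double)c.len2),
                        _["pixels"] = cut);
  }
  return List::create(_["found"] = false);
}
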