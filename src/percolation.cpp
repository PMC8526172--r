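#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Union-find with path compression + union by size.
struct UF {
  std::vector<int> parent, size;
  UF(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
};

// Bucketed pair enumeration: features i, j overlap in template-scaled
// coordinates (equal axis-aligned features map to unit discs / unit L1 balls).
// shape: 0 = ellipse (scaled distance < 2), 1 = rhombus (scaled L1 < 2).
static inline bool overlaps(double dx, double dy, double sa, double sb,
                            int shape) {
  double ux = dx / sa, uy = dy / sb;
  if (shape == 0) return ux * ux + uy * uy < 4.0;
  return std::fabs(ux) + std::fabs(uy) < 2.0;
}

// Does a cluster of overlapping discs span the box from y=0 to y=box?
// Discs of radius r at (cx, cy) in [0, box]^2, no periodicity.
// [[Rcpp::export]]
bool discs_span_cpp(NumericVector cx, NumericVector cy, double r, double box) {
  int n = cx.size();
  if (n == 0) return false;
  UF uf(n + 2);
  const int BOT = n, TOP = n + 1;
  double cell = 2.0 * r;
  int ncell = std::max(1, (int)std::floor(box / cell));
  double cw = box / ncell;
  std::vector<std::vector<int> > buckets(ncell * ncell);
  auto bidx = [&](double x) {
    int i = (int)std::floor(x / cw);
    if (i < 0) i = 0;
    if (i >= ncell) i = ncell - 1;
    return i;
  };
  for (int i = 0; i < n; ++i) {
    buckets[bidx(cx[i]) + ncell * bidx(cy[i])].push_back(i);
    if (cy[i] < r) uf.unite(i, BOT);
    if (cy[i] > box - r) uf.unite(i, TOP);
  }
  double r2 = 4.0 * r * r;
  for (int i = 0; i < n; ++i) {
    int bx = bidx(cx[i]), by = bidx(cy[i]);
    for (int ddx = -1; ddx <= 1; ++ddx) {
      for (int ddy = -1; ddy <= 1; ++ddy) {
        int qx = bx + ddx, qy = by + ddy;
        if (qx < 0 || qx >= ncell || qy < 0 || qy >= ncell) continue;
        for (int j : buckets[qx + ncell * qy]) {
          if (j <= i) continue;
          double dx = cx[i] - cx[j], dy = cy[i] - cy[j];
          if (dx * dx + dy * dy < r2) uf.unite(i, j);
        }
      }
    }
  }
  return uf.find(BOT) == uf.find(TOP);
}

// Transverse blockage in a periodic-y channel: true iff a connected union of
// overlapping features wraps the cylinder (some feature joins its own +Ly
// image), blocking every left-to-right path. Three periodic copies are used.
// [[Rcpp::export]]
bool channel_blockage_cpp(NumericVector cx, NumericVector cy, double sa,
                          double sb, int shape, double Ly) {
  int n = cx.size();
  if (n == 0) return false;
  // copies k = 0 (-Ly), 1 (base), 2 (+Ly); node = i + n*k
  UF uf(3 * n);
  // max interaction distance in real coordinates
  double reach_x = 2.0 * sa, reach_y = 2.0 * sb;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = cx[i] - cx[j];
      if (std::fabs(dx) >= reach_x) continue;
      for (int k = -1; k <= 1; ++k) {
        double dy = cy[i] - (cy[j] + k * Ly);
        if (std::fabs(dy) >= reach_y) continue;
        if (overlaps(dx, dy, sa, sb, shape)) {
          // copy c of i overlaps copy c+k of j for every c
          for (int c = 0; c < 3; ++c) {
            int cj = c + k;
            if (cj < 0 || cj > 2) continue;
            uf.unite(i + n * c, j + n * cj);
          }
        }
      }
    }
  }
  for (int i = 0; i < n; ++i)
    if (uf.find(i + n) == uf.find(i + 2 * n)) return true;
  return false;
}
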