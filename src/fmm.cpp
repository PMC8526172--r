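#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// First-order upwind (Godunov) fast marching on a regular grid.
// Grid is column-major with x as the fast index: cell (ix, iy) -> ix + nx*iy.
// x is the propagation axis (non-periodic); y may wrap periodically.
// Cells with v == 0 are never accepted and keep T = Inf.

static const double INF = std::numeric_limits<double>::infinity();

struct HeapEntry {
  double t;
  int idx;
  bool operator>(const HeapEntry& o) const { return t > o.t; }
};

// [[Rcpp::export]]
NumericVector fmm_solve_cpp(NumericVector v, int nx, int ny, double h,
                            bool periodic_y, IntegerVector init_idx,
                            NumericVector init_t) {
  const int n = nx * ny;
  NumericVector T(n, INF);
  std::vector<char> accepted(n, 0);
  std::priority_queue<HeapEntry, std::vector<HeapEntry>, std::greater<HeapEntry> > heap;

  for (int k = 0; k < init_idx.size(); ++k) {
    int idx = init_idx[k];
    if (idx < 0 || idx >= n) stop("source index out of range");
    if (v[idx] <= 0.0) continue;
    if (init_t[k] < T[idx]) {
      T[idx] = init_t[k];
      heap.push({init_t[k], idx});
    }
  }
  if (heap.empty()) return T;  // nothing reachable (e.g. all-zero speed)

  while (!heap.empty()) {
    HeapEntry e = heap.top();
    heap.pop();
    int idx = e.idx;
    if (accepted[idx]) continue;  // stale heap entry
    accepted[idx] = 1;

    int ix = idx % nx, iy = idx / nx;
    // relax the four neighbours
    for (int dir = 0; dir < 4; ++dir) {
      int jx = ix, jy = iy;
      if (dir == 0) jx = ix - 1;
      else if (dir == 1) jx = ix + 1;
      else if (dir == 2) jy = iy - 1;
      else jy = iy + 1;
      if (jx < 0 || jx >= nx) continue;
      if (jy < 0 || jy >= ny) {
        if (!periodic_y) continue;
        jy = (jy + ny) % ny;
      }
      int j = jx + nx * jy;
      if (accepted[j] || v[j] <= 0.0) continue;

      // upwind values along each axis from accepted neighbours
      double ta = INF, tb = INF;
      if (jx > 0 && accepted[j - 1]) ta = T[j - 1];
      if (jx < nx - 1 && accepted[j + 1]) ta = std::min(ta, T[j + 1]);
      int ym = jy - 1, yp = jy + 1;
      if (ym < 0) ym = periodic_y ? ny - 1 : -1;
      if (yp >= ny) yp = periodic_y ? 0 : -1;
      if (ym >= 0) { int jm = jx + nx * ym; if (accepted[jm]) tb = T[jm]; }
      if (yp >= 0) { int jp = jx + nx * yp; if (accepted[jp]) tb = std::min(tb, T[jp]); }

      double inv = h / v[j];
      double tnew;
      if (ta > tb) std::swap(ta, tb);
      if (tb == INF) {
        if (ta == INF) continue;
        tnew = ta + inv;
      } else if (tb - ta >= inv) {
        tnew = ta + inv;
      } else {
        double diff = ta - tb;
        tnew = 0.5 * (ta + tb + std::sqrt(2.0 * inv * inv - diff * diff));
      }
      if (tnew < T[j]) {
        T[j] = tnew;
        heap.push({tnew, j});
      }
    }
  }
  return T;
}

// Rightmost reached position per transverse row at each query time.
// Uses the per-row suffix minimum of T so "reached" means some cell at or
// beyond that x has arrival time <= t; position is sub-cell interpolated.
// Returns an ny x nt matrix; rows that are never reached give NA.
// [[Rcpp::export]]
NumericMatrix front_reach_cpp(NumericVector T, int nx, int ny, double h,
                              NumericVector times) {
  const int nt = times.size();
  NumericMatrix out(ny, nt);
  std::vector<double> S(nx);
  for (int iy = 0; iy < ny; ++iy) {
    double m = INF;
    for (int ix = nx - 1; ix >= 0; --ix) {
      m = std::min(m, T[ix + nx * iy]);
      S[ix] = m;
    }
    for (int k = 0; k < nt; ++k) {
      double t = times[k];
      if (S[0] > t) { out(iy, k) = NA_REAL; continue; }
      // largest ix with S[ix] <= t (S is non-decreasing in ix)
      int lo = 0, hi = nx - 1;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (S[mid] <= t) lo = mid; else hi = mid - 1;
      }
      double x = (lo + 0.5) * h;
      if (lo < nx - 1 && std::isfinite(S[lo + 1]) && S[lo + 1] > S[lo]) {
        double frac = (t - S[lo]) / (S[lo + 1] - S[lo]);
        if (frac < 0.0) frac = 0.0;
        if (frac > 1.0) frac = 1.0;
        x += frac * h;
      }
      out(iy, k) = x;
    }
  }
  return out;
}
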