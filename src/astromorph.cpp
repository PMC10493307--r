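#include <Rcpp.h>
using namespace Rcpp;

// Pixel-level inner loops of the image chain. Matrices are column-major
// (R layout); foreground is non-zero. Border handling: edge replication
// for the median filter, implicit background padding for thinning.

static inline int at(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0;
}

// Neighbours in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
// (rows grow downward: N is r-1).
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline void ring(const IntegerMatrix &m, int r, int c, int p[8]) {
  for (int k = 0; k < 8; ++k) p[k] = at(m, r + DR[k], c + DC[k]);
}

static inline int transitions(const int p[8]) {
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
  return a;
}

static inline int nsum(const int p[8]) {
  int b = 0;
  for (int k = 0; k < 8; ++k) b += p[k];
  return b;
}

// Zhang-Suen thinning with a staircase/2x2 cleanup pass so no 2x2
// foreground block survives while connectivity is preserved.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) m(i, j) = mask(i, j) ? 1 : 0;

  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  int p[8];
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          ring(m, i, j, p);
          int b = nsum(p);
          if (b < 2 || b > 6) continue;
          if (transitions(p) != 1) continue;
          // p[0]=N p[2]=E p[4]=S p[6]=W
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
    }
  }

  // Cleanup: a pixel inside a 2x2 foreground block is removed when its
  // deletion keeps the neighbourhood connected (one 0->1 ring transition)
  // and it is not an endpoint. Sequential, so connectivity is never broken.
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!m(i, j)) continue;
        bool block = false;
        // any of the four 2x2 blocks containing (i,j) fully set?
        for (int dj = -1; dj <= 0 && !block; ++dj)
          for (int di = -1; di <= 0 && !block; ++di) {
            int r0 = i + di, c0 = j + dj;
            if (at(m, r0, c0) && at(m, r0 + 1, c0) &&
                at(m, r0, c0 + 1) && at(m, r0 + 1, c0 + 1)) block = true;
          }
        if (!block) continue;
        ring(m, i, j, p);
        int b = nsum(p);
        if (b <= 1) continue;
        if (transitions(p) != 1) continue;
        m(i, j) = 0;
        changed = true;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = m(i, j) != 0;
  return out;
}

// 3x3 median filter, edge replication (ImageJ "Despeckle" semantics).
// [[Rcpp::export(name = ".cpp_median3")]]
NumericMatrix cpp_median3(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int c = j + dj; if (c < 0) c = 0; if (c >= nc) c = nc - 1;
        for (int di = -1; di <= 1; ++di) {
          int r = i + di; if (r < 0) r = 0; if (r >= nr) r = nr - 1;
          v[k++] = img(r, c);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}

// Stamp filled disks of radius rad (pixels, may be fractional) at the
// given centres (0-based row/col, fractional allowed) into a logical mask.
// [[Rcpp::export(name = ".cpp_stamp_disks")]]
LogicalMatrix cpp_stamp_disks(LogicalMatrix mask, NumericVector rows,
                              NumericVector cols, double rad) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out = clone(mask);
  double r2 = rad * rad;
  int w = (int)std::ceil(rad);
  for (int k = 0; k < rows.size(); ++k) {
    double cr = rows[k], cc = cols[k];
    int i0 = std::max(0, (int)std::floor(cr) - w - 1);
    int i1 = std::min(nr - 1, (int)std::ceil(cr) + w + 1);
    int j0 = std::max(0, (int)std::floor(cc) - w - 1);
    int j1 = std::min(nc - 1, (int)std::ceil(cc) + w + 1);
    for (int j = j0; j <= j1; ++j) {
      double dc = j - cc;
      for (int i = i0; i <= i1; ++i) {
        double dr = i - cr;
        if (dr * dr + dc * dc <= r2) out(i, j) = true;
      }
    }
  }
  return out;
}
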