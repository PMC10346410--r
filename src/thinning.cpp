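#include <Rcpp.h>
using namespace Rcpp;

// 8-neighborhood of (r, c), clockwise from north:
// P2 = (r-1, c), P3 = (r-1, c+1), P4 = (r, c+1), P5 = (r+1, c+1),
// P6 = (r+1, c), P7 = (r+1, c-1), P8 = (r, c-1), P9 = (r-1, c-1).
// Pixels outside the image count as background (implicit zero padding).
static inline int px(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

static inline void window(const IntegerMatrix& m, int r, int c, int* p) {
  p[0] = px(m, r - 1, c);      // P2
  p[1] = px(m, r - 1, c + 1);  // P3
  p[2] = px(m, r,     c + 1);  // P4
  p[3] = px(m, r + 1, c + 1);  // P5
  p[4] = px(m, r + 1, c);      // P6
  p[5] = px(m, r + 1, c - 1);  // P7
  p[6] = px(m, r,     c - 1);  // P8
  p[7] = px(m, r - 1, c - 1);  // P9
}

static inline int ncount(const int* p) {
  return p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
}

// 0 -> 1 transitions in the cyclic sequence P2, P3, ..., P9, P2
static inline int scount(const int* p) {
  int s = 0;
  for (int i = 0; i < 8; ++i)
    if (p[i] == 0 && p[(i + 1) % 8] == 1) ++s;
  return s;
}

// Two-subiteration parallel thinning. Each sub-iteration marks every
// foreground pixel whose window satisfies the deletion conditions, then
// deletes all marks at once; rounds repeat until a full round deletes
// nothing. Sub-iteration 1 requires P2*P4*P6 == 0 and P4*P6*P8 == 0;
// sub-iteration 2 requires P2*P4*P8 == 0 and P2*P6*P8 == 0. Both require
// 2 <= N(P1) <= 6 and S(P1) == 1.
// [[Rcpp::export]]
IntegerMatrix cpp_zhang_suen(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  const int h = m.nrow(), w = m.ncol();
  std::vector<int> mr, mc;
  mr.reserve(256); mc.reserve(256);
  bool changed = true;
  int p[8];
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      mr.clear(); mc.clear();
      for (int c = 0; c < w; ++c) {
        for (int r = 0; r < h; ++r) {
          if (m(r, c) != 1) continue;
          window(m, r, c, p);
          int n = ncount(p);
          if (n < 2 || n > 6) continue;
          if (scount(p) != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          mr.push_back(r); mc.push_back(c);
        }
      }
      if (!mr.empty()) {
        changed = true;
        for (size_t i = 0; i < mr.size(); ++i) m(mr[i], mc[i]) = 0;
      }
    }
  }
  return m;
}

// 8-connected component labeling; labels assigned in raster-scan order
// (row-major), so component k has the k-th smallest (row, col) seed.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (mask(r, c) != 1 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> rc = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = rc.first + dr, cc = rc.second + dc;
            if (rr < 0 || cc < 0 || rr >= h || cc >= w) continue;
            if (mask(rr, cc) == 1 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
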