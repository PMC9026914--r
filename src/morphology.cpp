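#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
using namespace Rcpp;

// 8-connected component labeling by iterative flood fill.
// Labels are assigned in column-major scan order of the first pixel met,
// so label order is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  lab.attr("n_objects") = next;
  return lab;
}

// Grayscale morphological reconstruction by dilation (marker under mask),
// 8-connectivity. Vincent's hybrid algorithm: forward raster scan, backward
// raster scan, then FIFO queue propagation.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_gray(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      J(i, j) = std::min(marker(i, j), mask(i, j));

  // neighbour offsets split by raster order (column-major): N- = already
  // visited when scanning forward, N+ = the rest.
  const int ndr[4] = {-1, -1, 0, 1};   // (dr, dc) pairs: left column trio + up
  const int ndc[4] = {-1, 0, -1, -1};
  // forward scan uses neighbours with (dc < 0) or (dc == 0 && dr < 0)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = J(i, j);
      for (int k = 0; k < 4; ++k) {
        int rr = i + ndr[k], cc = j + ndc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(i, j) = std::min(m, mask(i, j));
    }
  }
  std::queue<std::pair<int, int> > fifo;
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double m = J(i, j);
      for (int k = 0; k < 4; ++k) {
        int rr = i - ndr[k], cc = j - ndc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(i, j) = std::min(m, mask(i, j));
      // enqueue if some backward neighbour could still grow
      for (int k = 0; k < 4; ++k) {
        int rr = i - ndr[k], cc = j - ndc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < J(i, j) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(std::make_pair(i, j));
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
          J(rr, cc) = std::min(J(r, c), mask(rr, cc));
          fifo.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return J;
}

static inline int nb(const LogicalMatrix &m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px skeleton (8-connectivity preserved).
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          // neighbours p2..p9 clockwise from north (row-1)
          int p2 = nb(img, i - 1, j),     p3 = nb(img, i - 1, j + 1);
          int p4 = nb(img, i, j + 1),     p5 = nb(img, i + 1, j + 1);
          int p6 = nb(img, i + 1, j),     p7 = nb(img, i + 1, j - 1);
          int p8 = nb(img, i, j - 1),     p9 = nb(img, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < del.size(); ++k)
        img(del[k].first, del[k].second) = false;
      if (!del.empty()) changed = true;
    }
  }
  return img;
}
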