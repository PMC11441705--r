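#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, 8-connectivity.
// Hybrid raster/anti-raster algorithm with a FIFO propagation queue
// (Vincent 1993). The marker must satisfy marker <= mask element-wise;
// the R wrapper enforces this with pmin().

static inline int idx(int r, int c, int nr) { return c * nr + r; }

// [[Rcpp::export]]
NumericMatrix morph_reconstruct_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J = clone(marker);
  double *j = J.begin();
  double *m = mask.begin();

  // forward raster scan (column-major): already-visited 8-neighbours
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = j[idx(r, c, nr)];
      if (r > 0) v = std::max(v, j[idx(r - 1, c, nr)]);
      if (c > 0) {
        v = std::max(v, j[idx(r, c - 1, nr)]);
        if (r > 0) v = std::max(v, j[idx(r - 1, c - 1, nr)]);
        if (r < nr - 1) v = std::max(v, j[idx(r + 1, c - 1, nr)]);
      }
      j[idx(r, c, nr)] = std::min(v, m[idx(r, c, nr)]);
    }
  }

  std::queue<int> fifo;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // backward anti-raster scan
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = j[idx(r, c, nr)];
      if (r < nr - 1) v = std::max(v, j[idx(r + 1, c, nr)]);
      if (c < nc - 1) {
        v = std::max(v, j[idx(r, c + 1, nr)]);
        if (r < nr - 1) v = std::max(v, j[idx(r + 1, c + 1, nr)]);
        if (r > 0) v = std::max(v, j[idx(r - 1, c + 1, nr)]);
      }
      double out = std::min(v, m[idx(r, c, nr)]);
      j[idx(r, c, nr)] = out;
      // enqueue if some backward neighbour could still be raised
      bool push = false;
      int nbr[4][2] = {{r + 1, c}, {r, c + 1}, {r + 1, c + 1}, {r - 1, c + 1}};
      for (int k = 0; k < 4 && !push; ++k) {
        int rr = nbr[k][0], cc = nbr[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double jq = j[idx(rr, cc, nr)];
        if (jq < out && jq < m[idx(rr, cc, nr)]) push = true;
      }
      if (push) fifo.push(idx(r, c, nr));
    }
  }

  // FIFO propagation
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int r = p % nr, c = p / nr;
    double jp = j[p];
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int q = idx(rr, cc, nr);
      if (j[q] < jp && j[q] < m[q]) {
        j[q] = std::min(jp, m[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// Label 8-connected components of a logical mask. Background = 0,
// components numbered 1..n in scan order.

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(idx(r, c, nr));
      while (!q.empty()) {
        int p = q.front();
        q.pop();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = pr + dr[k], cc = pc + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(idx(rr, cc, nr));
          }
        }
      }
    }
  }
  return lab;
}
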