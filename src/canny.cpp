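#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Symmetric (half-sample) reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median3(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr)
          w[k++] = x(refl(r + dr, nr), refl(c + dc, nc));
      std::nth_element(w, w + 4, w + 9);
      out(r, c) = w[4];
    }
  }
  return out;
}

// Separable convolution with a symmetric 1-D kernel, reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix x, NumericVector kernel) {
  int nr = x.nrow(), nc = x.ncol();
  int radius = (kernel.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass (along rows within a column)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int d = -radius; d <= radius; ++d)
        s += kernel[d + radius] * x(refl(r + d, nr), c);
      tmp(r, c) = s;
    }
  // horizontal pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int d = -radius; d <= radius; ++d)
        s += kernel[d + radius] * tmp(r, refl(c + d, nc));
      out(r, c) = s;
    }
  return out;
}

// 3x3 Sobel derivatives with reflected borders. gx is the derivative along
// columns (increasing column index), gy along rows (increasing row index).
// [[Rcpp::export]]
List cpp_sobel(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc);
  static const double smooth[3] = {1.0, 2.0, 1.0};
  static const double diff[3]   = {-1.0, 0.0, 1.0};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double sx = 0.0, sy = 0.0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          double v = x(refl(r + dr, nr), refl(c + dc, nc));
          sx += smooth[dr + 1] * diff[dc + 1] * v;
          sy += diff[dr + 1] * smooth[dc + 1] * v;
        }
      gx(r, c) = sx;
      gy(r, c) = sy;
    }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Direction sector: quantize to 0 (horizontal gradient), 1 (45 deg),
// 2 (vertical), 3 (135 deg); boundaries at odd multiples of 22.5 deg.
static inline int sector_of(double theta) {
  const double pi = 3.14159265358979323846;
  double a = theta;
  while (a < 0) a += pi;        // fold to [0, pi)
  while (a >= pi) a -= pi;
  double deg = a * 180.0 / pi;
  if (deg < 22.5 || deg >= 157.5) return 0;
  if (deg < 67.5)  return 1;
  if (deg < 112.5) return 2;
  return 3;
}

// Non-maximum suppression along the quantized gradient direction; ties
// (>= both neighbours) are kept; out-of-grid neighbours are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_nms(NumericMatrix mag, NumericMatrix dir) {
  int nr = mag.nrow(), nc = mag.ncol();
  if (dir.nrow() != nr || dir.ncol() != nc)
    stop("magnitude and direction grids must have identical dimensions");
  // neighbour offsets (dr, dc) per sector, along the gradient direction
  static const int off[4][2] = {{0, 1}, {1, 1}, {1, 0}, {1, -1}};
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = mag(r, c);
      int s = sector_of(dir(r, c));
      int dr = off[s][0], dc = off[s][1];
      bool keep = true;
      int r1 = r + dr, c1 = c + dc;
      if (r1 >= 0 && r1 < nr && c1 >= 0 && c1 < nc && m < mag(r1, c1))
        keep = false;
      int r2 = r - dr, c2 = c - dc;
      if (keep && r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && m < mag(r2, c2))
        keep = false;
      out(r, c) = keep ? m : 0.0;
    }
  return out;
}

// Hysteresis thresholding: strong = mag >= high, weak = low <= mag < high;
// edges are strong pixels plus weak pixels 8-connected to a strong pixel
// through weak/strong chains.
// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(NumericMatrix mag, double low, double high) {
  if (!(low < high)) stop("low threshold must be smaller than high threshold");
  int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mag(r, c) >= high && !out(r, c)) {
        out(r, c) = true;
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
              if (dr == 0 && dc == 0) continue;
              int r2 = rr + dr, c2 = cc + dc;
              if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
              if (!out(r2, c2) && mag(r2, c2) >= low) {
                out(r2, c2) = true;
                stack.push_back(r2 + c2 * nr);
              }
            }
        }
      }
  return out;
}

// Count connected components of TRUE pixels (connectivity 4 or 8).
// [[Rcpp::export]]
int cpp_count_components(LogicalMatrix x, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = x.nrow(), nc = x.ncol();
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> stack;
  int count = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      size_t idx = (size_t)r + (size_t)c * nr;
      if (!x(r, c) || seen[idx]) continue;
      ++count;
      seen[idx] = 1;
      stack.push_back((int)idx);
      while (!stack.empty()) {
        int id = stack.back(); stack.pop_back();
        int rr = id % nr, cc = id / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            size_t i2 = (size_t)r2 + (size_t)c2 * nr;
            if (x(r2, c2) && !seen[i2]) {
              seen[i2] = 1;
              stack.push_back((int)i2);
            }
          }
      }
    }
  return count;
}
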