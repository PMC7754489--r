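#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect (symmetric, edge duplicated) index into [0, n)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

//' @title 2D sliding median filter (exact, double precision)
//' @description Median of a (window x window) neighbourhood around every
//'   pixel, with symmetric reflect padding at the borders. The window must
//'   be odd; callers round even windows up.
//' @param x numeric matrix
//' @param window odd window side length, >= 3
//' @return matrix of the same shape
//' @keywords internal
// [[Rcpp::export(name = ".median_filter2d")]]
NumericMatrix median_filter2d(NumericMatrix x, int window) {
  int nr = x.nrow(), nc = x.ncol();
  if (window < 3 || window % 2 == 0)
    stop("window must be odd and >= 3");
  if (window > nr || window > nc)
    stop("window larger than image");
  int h = window / 2;
  int wlen = window * window;
  NumericMatrix out(nr, nc);
  std::vector<int> ridx(nr + 2 * h), cidx(nc + 2 * h);
  for (int i = -h; i < nr + h; ++i) ridx[i + h] = reflect_idx(i, nr);
  for (int j = -h; j < nc + h; ++j) cidx[j + h] = reflect_idx(j, nc);
  std::vector<double> buf(wlen);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        const double* col = &x(0, cidx[j + dj + h]);
        for (int di = -h; di <= h; ++di)
          buf[k++] = col[ridx[i + di + h]];
      }
      std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.end());
      out(i, j) = buf[wlen / 2];
    }
  }
  return out;
}

//' @title 2D sliding median filter (16-bit two-level histogram)
//' @description Huang-style sliding-histogram median with the image
//'   quantized to 65536 levels over its value range; reflect padding.
//'   Output precision is (max - min) / 65535 of the input range, which
//'   is why callers reserve it for large images where the exact filter
//'   is too slow.
//' @param x numeric matrix
//' @param window odd window side length, >= 3
//' @return matrix of the same shape
//' @keywords internal
// [[Rcpp::export(name = ".median_filter2d_hist")]]
NumericMatrix median_filter2d_hist(NumericMatrix x, int window) {
  int nr = x.nrow(), nc = x.ncol();
  if (window < 3 || window % 2 == 0)
    stop("window must be odd and >= 3");
  if (window > nr || window > nc)
    stop("window larger than image");
  int h = window / 2;
  double mn = R_PosInf, mx = R_NegInf;
  for (NumericMatrix::iterator it = x.begin(); it != x.end(); ++it) {
    if (*it < mn) mn = *it;
    if (*it > mx) mx = *it;
  }
  NumericMatrix out(nr, nc);
  if (!(mx > mn)) {                      // constant image
    std::fill(out.begin(), out.end(), mn);
    return out;
  }
  const int NB = 65536;
  double scale = (NB - 1) / (mx - mn);
  std::vector<int> q((size_t)nr * nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    int* qc = &q[(size_t)j * nr];
    for (int i = 0; i < nr; ++i) {
      int b = (int)std::floor((col[i] - mn) * scale + 0.5);
      if (b < 0) b = 0;
      if (b >= NB) b = NB - 1;
      qc[i] = b;
    }
  }
  std::vector<int> ridx(nr + 2 * h), cidx(nc + 2 * h);
  for (int i = -h; i < nr + h; ++i) ridx[i + h] = reflect_idx(i, nr);
  for (int j = -h; j < nc + h; ++j) cidx[j + h] = reflect_idx(j, nc);
  std::vector<int> fine(NB), coarse(256);
  int k = (window * window) / 2 + 1;     // 1-based median rank
  for (int j = 0; j < nc; ++j) {
    std::fill(fine.begin(), fine.end(), 0);
    std::fill(coarse.begin(), coarse.end(), 0);
    for (int dj = -h; dj <= h; ++dj) {
      const int* qc = &q[(size_t)cidx[j + dj + h] * nr];
      for (int di = -h; di <= h; ++di) {
        int b = qc[ridx[di + h]];
        ++fine[b];
        ++coarse[b >> 8];
      }
    }
    for (int i = 0; i < nr; ++i) {
      if (i > 0) {
        int rrem = ridx[i - 1 - h + h], radd = ridx[i + h + h];
        for (int dj = -h; dj <= h; ++dj) {
          const int* qc = &q[(size_t)cidx[j + dj + h] * nr];
          int b = qc[rrem];
          --fine[b];
          --coarse[b >> 8];
          b = qc[radd];
          ++fine[b];
          ++coarse[b >> 8];
        }
      }
      int cnt = 0, cb = 0;
      while (cnt + coarse[cb] < k) { cnt += coarse[cb]; ++cb; }
      int b = cb << 8;
      while (cnt + fine[b] < k) { cnt += fine[b]; ++b; }
      out(i, j) = mn + b / scale;
    }
  }
  return out;
}

//' @title Connected-component labelling of a binary matrix
//' @description Labels connected foreground components with consecutive
//'   integers starting at 1, in raster-scan discovery order. Supports
//'   4- and 8-connectivity.
//' @param mask integer/logical matrix, nonzero = foreground
//' @param connectivity 4 or 8
//' @return integer matrix of labels (0 = background)
//' @keywords internal
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        stack.clear();
        stack.push_back(std::make_pair(i, j));
        lab(i, j) = next;
        while (!stack.empty()) {
          std::pair<int, int> p = stack.back();
          stack.pop_back();
          for (int q = 0; q < nnb; ++q) {
            int ii = p.first + dr8[q], jj = p.second + dc8[q];
            if (ii >= 0 && ii < nr && jj >= 0 && jj < nc &&
                mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}
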