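#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// reflect an out-of-range index into [0, n-1] (mirror without repeating the edge)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Median filter with a disk footprint of the given radius; edges by reflection.
// radius 0 is the identity.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0) return clone(img);

  // disk footprint offsets
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  int k = (int)dr.size();

  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int m = 0; m < k; ++m) {
        int ii = reflect_idx(i + dr[m], nr);
        int jj = reflect_idx(j + dc[m], nc);
        buf[m] = img(ii, jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Connected-component labelling of a logical mask (connectivity 4 or 8).
// Labels are 1-based in raster scan order of component discovery.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int n8r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int n8c[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int n4r[4] = {-1, 0, 0, 1};
  int n4c[4] = {0, -1, 1, 0};
  int *drp = (connectivity == 8) ? n8r : n4r;
  int *dcp = (connectivity == 8) ? n8c : n4c;
  int nn = (connectivity == 8) ? 8 : 4;

  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int m = 0; m < nn; ++m) {
          int qi = pi + drp[m], qj = pj + dcp[m];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: any background region not 4-connected to the image border
// becomes foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> reach((size_t)nr * nc, 0);
  std::vector<int> stack;
  // seed from border background pixels
  for (int i = 0; i < nr; ++i) {
    for (int j : {0, nc - 1}) {
      if (!mask(i, j) && !reach[i + (size_t)j * nr]) {
        reach[i + (size_t)j * nr] = 1;
        stack.push_back(i + j * nr);
      }
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i : {0, nr - 1}) {
      if (!mask(i, j) && !reach[i + (size_t)j * nr]) {
        reach[i + (size_t)j * nr] = 1;
        stack.push_back(i + j * nr);
      }
    }
  }
  int drp[4] = {-1, 0, 0, 1}, dcp[4] = {0, -1, 1, 0};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pi = p % nr, pj = p / nr;
    for (int m = 0; m < 4; ++m) {
      int qi = pi + drp[m], qj = pj + dcp[m];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      size_t q = qi + (size_t)qj * nr;
      if (!mask(qi, qj) && !reach[q]) {
        reach[q] = 1;
        stack.push_back(qi + qj * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reach[i + (size_t)j * nr];
  return out;
}
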