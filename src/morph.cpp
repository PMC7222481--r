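#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Grayscale erosion/dilation by a flat disc, exact, via decomposition of the
// disc into horizontal chords: for each row offset dy the disc contributes a
// centred segment of half-width floor(sqrt(r^2 - dy^2)); the erosion is the
// minimum over dy of the 1D min-filtered row i+dy.  Each 1D filter uses the
// van Herk/Gil-Werman running scheme, O(n) per row independent of width.
// Borders are handled by reflection.

static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// 1D min (or max) filter of x with window half-width w, reflected borders
static void run_filter_1d(const std::vector<double> &x, std::vector<double> &out,
                          int w, bool mini) {
  const int n = (int)x.size();
  const int win = 2 * w + 1;
  if (w == 0) { out = x; return; }
  // padded source with reflection
  std::vector<double> s(n + 2 * w);
  for (int i = 0; i < n + 2 * w; ++i) s[i] = x[reflect(i - w, n)];
  const int m = (int)s.size();
  std::vector<double> pre(m), suf(m);
  for (int i = 0; i < m; ++i) {
    if (i % win == 0) pre[i] = s[i];
    else pre[i] = mini ? std::min(pre[i - 1], s[i]) : std::max(pre[i - 1], s[i]);
  }
  for (int i = m - 1; i >= 0; --i) {
    if (i == m - 1 || (i + 1) % win == 0) suf[i] = s[i];
    else suf[i] = mini ? std::min(suf[i + 1], s[i]) : std::max(suf[i + 1], s[i]);
  }
  for (int i = 0; i < n; ++i) {
    int lo = i, hi = i + 2 * w;          // window [lo, hi] in padded coords
    out[i] = mini ? std::min(suf[lo], pre[hi]) : std::max(suf[lo], pre[hi]);
  }
}

static NumericMatrix disc_morph(const NumericMatrix &img, int radius, bool mini) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), mini ? R_PosInf : R_NegInf);
  std::vector<double> row(nc), filt(nc);
  // chord half-widths per row offset
  std::vector<int> halfw(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy)
    halfw[dy + radius] = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
  for (int dy = -radius; dy <= radius; ++dy) {
    int w = halfw[dy + radius];
    for (int i = 0; i < nr; ++i) {
      int src = reflect(i + dy, nr);
      for (int j = 0; j < nc; ++j) row[j] = img(src, j);
      run_filter_1d(row, filt, w, mini);
      if (mini) {
        for (int j = 0; j < nc; ++j)
          if (filt[j] < out(i, j)) out(i, j) = filt[j];
      } else {
        for (int j = 0; j < nc; ++j)
          if (filt[j] > out(i, j)) out(i, j) = filt[j];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".erode_disc_core")]]
NumericMatrix erode_disc_core(NumericMatrix img, int radius) {
  return disc_morph(img, radius, true);
}

// [[Rcpp::export(name = ".dilate_disc_core")]]
NumericMatrix dilate_disc_core(NumericMatrix img, int radius) {
  return disc_morph(img, radius, false);
}

// [[Rcpp::export(name = ".open_disc_core")]]
NumericMatrix open_disc_core(NumericMatrix img, int radius) {
  return disc_morph(disc_morph(img, radius, true), radius, false);
}
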