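#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson-normalized cross-correlation of tpl against every valid placement
// in img. Output (H-th+1) x (W-tw+1); out(i,j) is the correlation with the
// window whose top-left corner is (i,j) (0-based). Zero-variance windows or
// templates correlate as 0.
// [[Rcpp::export]]
NumericMatrix ncc_match_cpp(NumericMatrix img, NumericMatrix tpl) {
  const int H = img.nrow(), W = img.ncol();
  const int th = tpl.nrow(), tw = tpl.ncol();
  const int oh = H - th + 1, ow = W - tw + 1;
  const int n = th * tw;
  const double eps = 1e-12;

  double tsum = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tsum += tpl(i, j);
  const double tmean = tsum / n;
  double tvar = 0.0;
  std::vector<double> tz((size_t)n);
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      double v = tpl(i, j) - tmean;
      tz[(size_t)j * th + i] = v;
      tvar += v * v;
    }

  NumericMatrix out(oh, ow);
  if (tvar <= eps) return out;  // flat template: correlation defined as 0

  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      double wsum = 0.0, wsq = 0.0, cross = 0.0;
      for (int j = 0; j < tw; ++j) {
        const double* col = &img(0, oj + j);
        const double* tzc = &tz[(size_t)j * th];
        for (int i = 0; i < th; ++i) {
          double v = col[oi + i];
          wsum += v;
          wsq += v * v;
          cross += v * tzc[i];
        }
      }
      double wvar = wsq - wsum * wsum / n;
      double r = 0.0;
      if (wvar > eps) {
        r = cross / std::sqrt(wvar * tvar);
        if (r > 1.0) r = 1.0;
        if (r < -1.0) r = -1.0;
      }
      out(oi, oj) = r;
    }
  }
  return out;
}
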