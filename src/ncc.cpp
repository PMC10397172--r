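#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-normalized cross-correlation of `templ` (h x w) against `image`
// (H x W) over candidate top-left positions x in [x0, x1], y in [y0, y1]
// (0-based pixel coordinates). Returns a (y1-y0+1) x (x1-x0+1) score
// matrix in [-1, 1]; positions where either the template or the image
// patch is (near-)constant score NA.
//
// Matrices are R column-major: element (row r, col c) = m[r + c*H],
// with r = y and c = x under the package's top-left origin convention.
// [[Rcpp::export]]
NumericMatrix ncc_search(const NumericMatrix& image, const NumericMatrix& templ,
                         int x0, int x1, int y0, int y1) {
  const int H = image.nrow(), W = image.ncol();
  const int h = templ.nrow(), w = templ.ncol();
  if (h < 1 || w < 1) stop("empty template");
  if (x0 > x1 || y0 > y1) stop("empty search range");
  if (x0 < 0 || y0 < 0 || x1 + w > W || y1 + h > H)
    stop("search range places template outside image");

  const double n = (double)h * (double)w;
  double tsum = 0.0, tsum2 = 0.0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      const double v = templ(r, c);
      tsum += v; tsum2 += v * v;
    }
  const double tmean = tsum / n;
  const double tvar = tsum2 - tsum * tsum / n; // n * var
  const double eps = 1e-12;
  const bool tflat = tvar < eps * n;

  NumericMatrix out(y1 - y0 + 1, x1 - x0 + 1);
  for (int x = x0; x <= x1; ++x) {
    for (int y = y0; y <= y1; ++y) {
      double s = 0.0, s2 = 0.0, st = 0.0;
      for (int c = 0; c < w; ++c) {
        const double* icol = &image(0, x + c);
        const double* tcol = &templ(0, c);
        for (int r = 0; r < h; ++r) {
          const double v = icol[y + r];
          s += v; s2 += v * v; st += v * tcol[r];
        }
      }
      const double pvar = s2 - s * s / n;
      if (tflat || pvar < eps * n) {
        out(y - y0, x - x0) = NA_REAL;
      } else {
        const double cov = st - s * tmean;
        out(y - y0, x - x0) = cov / std::sqrt(pvar * tvar);
      }
    }
  }
  return out;
}
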