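#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of a matrix at fractional 0-based (row, col) positions.
// Positions outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(const NumericMatrix& img,
                                  const NumericVector& row,
                                  const NumericVector& col,
                                  double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = row.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double r = row[i], c = col[i];
    if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) {
      out[i] = fill;
      continue;
    }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = r0 + 1 < nr ? r0 + 1 : r0;
    int c1 = c0 + 1 < nc ? c0 + 1 : c0;
    double fr = r - r0, fc = c - c0;
    double v00 = img(r0, c0), v01 = img(r0, c1);
    double v10 = img(r1, c0), v11 = img(r1, c1);
    out[i] = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
             fr * ((1 - fc) * v10 + fc * v11);
  }
  return out;
}

// Parallel-beam Radon transform. Detector coordinate t and ray parameter s
// both run over the pixel index range centred on the grid centre; step 1 px.
// Returns ndet x nang sinogram in units of (value * px).
// [[Rcpp::export]]
NumericMatrix cpp_radon(const NumericMatrix& img, const NumericVector& angles,
                        double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ndet = std::max(nr, nc);
  const int nang = angles.size();
  const double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  const double t0 = -(ndet - 1) / 2.0;
  NumericMatrix sino(ndet, nang);
  for (int a = 0; a < nang; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int d = 0; d < ndet; ++d) {
      double t = t0 + d;
      double acc = 0.0;
      for (int s = 0; s < ndet; ++s) {
        double sv = t0 + s;
        // x along columns, y along rows
        double x = t * ca - sv * sa + cc;
        double y = t * sa + sv * ca + cr;
        double v;
        if (x < 0.0 || y < 0.0 || x > nc - 1.0 || y > nr - 1.0) {
          v = fill;
        } else {
          int r0 = (int)std::floor(y), c0 = (int)std::floor(x);
          int r1 = r0 + 1 < nr ? r0 + 1 : r0;
          int c1 = c0 + 1 < nc ? c0 + 1 : c0;
          double fr = y - r0, fc = x - c0;
          v = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
              fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
        }
        acc += v;
      }
      sino(d, a) = acc;
    }
  }
  return sino;
}

// Backprojection of a filtered sinogram (ndet x nang) onto an n x n grid.
// Linear interpolation along the detector axis; caller applies pi/(2*nang).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix& sino,
                              const NumericVector& angles, int n) {
  const int ndet = sino.nrow();
  const int nang = angles.size();
  const double c = (n - 1) / 2.0;
  const double t0 = -(ndet - 1) / 2.0;
  NumericMatrix out(n, n);
  for (int a = 0; a < nang; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int rr = 0; rr < n; ++rr) {
      double y = rr - c;
      for (int cc2 = 0; cc2 < n; ++cc2) {
        double x = cc2 - c;
        double t = x * ca + y * sa - t0;   // detector-bin coordinate
        if (t < 0.0 || t > ndet - 1.0) continue;
        int i0 = (int)std::floor(t);
        int i1 = i0 + 1 < ndet ? i0 + 1 : i0;
        double f = t - i0;
        out(rr, cc2) += (1 - f) * sino(i0, a) + f * sino(i1, a);
      }
    }
  }
  return out;
}
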