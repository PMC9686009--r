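#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3x3 same-padding (zero) convolution primitives for the toy translator.
// Tensors are R arrays in (H, W, C) column-major layout; weights are
// (3, 3, Cin, Cout) with the first index running over row offsets.
// Implemented as shift-and-accumulate over the 9 taps so the inner loops
// are contiguous and auto-vectorise.

static inline int dim3(const NumericVector& x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_fwd(const NumericVector& x, const NumericVector& w,
                              const NumericVector& b) {
  const int H = dim3(x, 0), W = dim3(x, 1), Cin = dim3(x, 2);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double* yc = py + static_cast<size_t>(co) * H * W;
    const double bias = b[co];
    for (size_t k = 0; k < static_cast<size_t>(H) * W; ++k) yc[k] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = px + static_cast<size_t>(ci) * H * W;
      const double* wc = pw + (static_cast<size_t>(co) * Cin + ci) * 9;
      for (int dj = -1; dj <= 1; ++dj) {
        const int j0 = dj < 0 ? 1 : 0;
        const int j1 = dj > 0 ? W - 2 : W - 1;
        for (int di = -1; di <= 1; ++di) {
          const double wv = wc[(dj + 1) * 3 + (di + 1)];
          if (wv == 0.0) continue;
          const int i0 = di < 0 ? 1 : 0;
          const int i1 = di > 0 ? H - 2 : H - 1;
          for (int j = j0; j <= j1; ++j) {
            double* yrow = yc + static_cast<size_t>(j) * H;
            const double* xrow = xc + static_cast<size_t>(j + dj) * H + di;
            for (int i = i0; i <= i1; ++i) yrow[i] += wv * xrow[i];
          }
        }
      }
    }
  }
  return y;
}

// Backward pass: given x, w and upstream gradient dy, returns list(dx, dw, db).
// [[Rcpp::export]]
List cpp_conv3x3_bwd(const NumericVector& x, const NumericVector& w,
                     const NumericVector& dy) {
  const int H = dim3(x, 0), W = dim3(x, 1), Cin = dim3(x, 2);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * Cin);
  NumericVector dw(static_cast<R_xlen_t>(9) * Cin * Cout);
  NumericVector db(Cout);
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  dw.attr("dim") = wd;
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  double* pdw = dw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = pdy + static_cast<size_t>(co) * H * W;
    double accb = 0.0;
    for (size_t k = 0; k < static_cast<size_t>(H) * W; ++k) accb += gc[k];
    db[co] = accb;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = px + static_cast<size_t>(ci) * H * W;
      const double* wc = pw + (static_cast<size_t>(co) * Cin + ci) * 9;
      double* dwc = pdw + (static_cast<size_t>(co) * Cin + ci) * 9;
      double* dxc = pdx + static_cast<size_t>(ci) * H * W;
      for (int dj = -1; dj <= 1; ++dj) {
        const int j0 = dj < 0 ? 1 : 0;
        const int j1 = dj > 0 ? W - 2 : W - 1;
        for (int di = -1; di <= 1; ++di) {
          const int i0 = di < 0 ? 1 : 0;
          const int i1 = di > 0 ? H - 2 : H - 1;
          const int widx = (dj + 1) * 3 + (di + 1);
          const double wv = wc[widx];
          double accw = 0.0;
          for (int j = j0; j <= j1; ++j) {
            const double* grow = gc + static_cast<size_t>(j) * H;
            const double* xrow = xc + static_cast<size_t>(j + dj) * H + di;
            double* dxrow = pdx == nullptr ? nullptr
                            : dxc + static_cast<size_t>(j + dj) * H + di;
            for (int i = i0; i <= i1; ++i) {
              const double g = grow[i];
              accw += xrow[i] * g;
              dxrow[i] += wv * g;
            }
          }
          dwc[widx] += accw;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
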