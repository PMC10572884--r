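// Hot loops of the convolution layers: im2col / col2im with 'same'
// (zero) padding and optional dilation. Layout matches the R side:
// images are h x w x c column-major arrays, patch matrices are
// (h*w) x (k*k*c) with kernel-offset-major, channel-minor column blocks.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int h, int w, int cin, int k,
                         int dilation) {
  const int p = dilation * (k - 1) / 2;
  const int hw = h * w;
  NumericMatrix X(hw, k * k * cin);
  int n = 0;
  for (int joff = 0; joff < k; ++joff) {
    for (int ioff = 0; ioff < k; ++ioff, ++n) {
      const int dr = ioff * dilation - p;
      const int dc = joff * dilation - p;
      for (int c = 0; c < cin; ++c) {
        double* col = &X(0, n * cin + c);
        const double* src = &x[(R_xlen_t)c * hw];
        const int j0 = std::max(0, -dc), j1 = std::min(w, w - dc);
        const int i0 = std::max(0, -dr), i1 = std::min(h, h - dr);
        for (int j = j0; j < j1; ++j) {
          const double* s = src + (R_xlen_t)(j + dc) * h + dr;
          double* d = col + (R_xlen_t)j * h;
          for (int i = i0; i < i1; ++i) d[i] = s[i];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dX, int h, int w, int cin, int k,
                         int dilation) {
  const int p = dilation * (k - 1) / 2;
  const int hw = h * w;
  NumericVector dx((R_xlen_t)hw * cin);
  int n = 0;
  for (int joff = 0; joff < k; ++joff) {
    for (int ioff = 0; ioff < k; ++ioff, ++n) {
      const int dr = ioff * dilation - p;
      const int dc = joff * dilation - p;
      for (int c = 0; c < cin; ++c) {
        const double* col = &dX(0, n * cin + c);
        double* dst = &dx[(R_xlen_t)c * hw];
        const int j0 = std::max(0, -dc), j1 = std::min(w, w - dc);
        const int i0 = std::max(0, -dr), i1 = std::min(h, h - dr);
        for (int j = j0; j < j1; ++j) {
          double* d = dst + (R_xlen_t)(j + dc) * h + dr;
          const double* s = col + (R_xlen_t)j * h;
          for (int i = i0; i < i1; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dx;
}
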