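// Hot path of the batched convolution: im2col / col2im lowering for
// k x k same-padded convolutions on (H, W, N, C) tensors (channels last,
// column-major). The matrix products themselves run through R's BLAS.
#include <Rcpp.h>
using namespace Rcpp;

// x: numeric vector holding an (H, W, N, C) array.
// Returns the (H*W*N) x (k*k*C) patch matrix; column block (dj*k + di)*C + c
// holds input channel c shifted by (di - p, dj - p), zero outside the frame.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix out(rows, (R_xlen_t)k * k * C);
  const double* px = x.begin();
  double* pout = out.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int blk = (dj * k + di) * C;
      for (int c = 0; c < C; ++c) {
        double* dst = pout + (R_xlen_t)(blk + c) * rows;
        const double* src = px + (R_xlen_t)c * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double* srcn = src + (R_xlen_t)n * H * W;
          double* dstn = dst + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dj - p;
            double* dcol = dstn + (R_xlen_t)w * H;
            if (ws < 0 || ws >= W) {
              std::fill(dcol, dcol + H, 0.0);
              continue;
            }
            const double* scol = srcn + (R_xlen_t)ws * H;
            const int h0 = std::max(0, p - di);
            const int h1 = std::min(H, H + p - di);
            for (int h = 0; h < h0; ++h) dcol[h] = 0.0;
            for (int h = h0; h < h1; ++h) dcol[h] = scol[h + di - p];
            for (int h = h1; h < H; ++h) dcol[h] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-accumulate the patch-matrix gradient back
// onto an (H, W, N, C) tensor.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * N * C);  // zero-initialized
  const double* pc = cols.begin();
  double* po = out.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int blk = (dj * k + di) * C;
      for (int c = 0; c < C; ++c) {
        const double* src = pc + (R_xlen_t)(blk + c) * rows;
        double* dst = po + (R_xlen_t)c * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double* srcn = src + (R_xlen_t)n * H * W;
          double* dstn = dst + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int wd = w + dj - p;
            if (wd < 0 || wd >= W) continue;
            const double* scol = srcn + (R_xlen_t)w * H;
            double* dcol = dstn + (R_xlen_t)wd * H;
            const int h0 = std::max(0, p - di);
            const int h1 = std::min(H, H + p - di);
            for (int h = h0; h < h1; ++h) dcol[h + di - p] += scol[h];
          }
        }
      }
    }
  }
  return out;
}
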