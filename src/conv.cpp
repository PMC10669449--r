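// Core raster kernels: same-padding 2-D convolution (forward + backward)
// via im2col and BLAS GEMM, and 8-connected component labelling.
//
// Layout conventions (shared with the R side):
//   * feature maps are H x W x C arma::cube (column-major, slice = channel)
//   * a conv weight is a (Cout) x (Cin*k*k) matrix; the column for input
//     channel ci and kernel offset (ky, kx) from the top-left corner is
//     ci*k*k + kx*k + ky (0-based).  Output pixel (r, c) reads input pixel
//     (r + ky - p, c + kx - p) with p = (k-1)/2 and zero padding.
//
// im2col uses a pixel-major patch matrix (H*B rows, Cin*k*k columns) so
// every inner copy is a contiguous column segment; work is chunked over
// image columns to bound memory at large image sizes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// fill `cols` ((H*B) x Cin*k*k) for output columns [c0, c0+B)
static void im2col_block(const arma::cube& x, int k, int c0, int B,
                         arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  cols.zeros();
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        double* dst0 = cols.colptr(ci * k * k + kx * k + ky);
        const int r_lo = std::max(0, p - ky);
        const int r_hi = std::min(H, H + p - ky);
        for (int b = 0; b < B; ++b) {
          const int ic = c0 + b + kx - p;        // input column
          if (ic < 0 || ic >= W) continue;
          const double* src = x.slice_colptr(ci, ic) + (r_lo + ky - p);
          std::copy(src, src + (r_hi - r_lo), dst0 + (size_t)b * H + r_lo);
        }
      }
    }
  }
}

// scatter-add the transpose operation of im2col_block
static void col2im_block(arma::cube& dx, int k, int c0, int B,
                         const arma::mat& dcols) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int p = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const double* src0 = dcols.colptr(ci * k * k + kx * k + ky);
        const int r_lo = std::max(0, p - ky);
        const int r_hi = std::min(H, H + p - ky);
        for (int b = 0; b < B; ++b) {
          const int ic = c0 + b + kx - p;
          if (ic < 0 || ic >= W) continue;
          double* dst = dx.slice_colptr(ci, ic) + (r_lo + ky - p);
          const double* src = src0 + (size_t)b * H + r_lo;
          const int n = r_hi - r_lo;
          for (int i = 0; i < n; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& Wm,
                      const arma::vec& bias, int k, int block = 128) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = Wm.n_rows;
  if ((int)Wm.n_cols != C * k * k)
    stop("weight matrix has %d columns, expected %d", (int)Wm.n_cols,
         C * k * k);
  if ((int)bias.n_elem != Cout) stop("bias length mismatch");
  arma::cube y(H, W, Cout);
  arma::mat cols((size_t)H * std::min(block, W), C * k * k);
  for (int c0 = 0; c0 < W; c0 += block) {
    const int B = std::min(block, W - c0);
    if ((int)cols.n_rows != H * B) cols.set_size((size_t)H * B, C * k * k);
    im2col_block(x, k, c0, B, cols);
    arma::mat out = cols * Wm.t();           // (H*B) x Cout
    out.each_row() += bias.t();
    for (int co = 0; co < Cout; ++co)
      std::copy(out.colptr(co), out.colptr(co) + (size_t)H * B,
                y.slice_colptr(co, c0));
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::mat& Wm,
                         const arma::cube& dy, int k, int block = 128) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = Wm.n_rows;
  arma::mat dW(Cout, C * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::mat cols((size_t)H * std::min(block, W), C * k * k);
  arma::mat dyb((size_t)H * std::min(block, W), Cout);
  for (int c0 = 0; c0 < W; c0 += block) {
    const int B = std::min(block, W - c0);
    if ((int)cols.n_rows != H * B) {
      cols.set_size((size_t)H * B, C * k * k);
      dyb.set_size((size_t)H * B, Cout);
    }
    im2col_block(x, k, c0, B, cols);
    for (int co = 0; co < Cout; ++co)
      std::copy(dy.slice_colptr(co, c0), dy.slice_colptr(co, c0) +
                  (size_t)H * B, dyb.colptr(co));
    dW += dyb.t() * cols;
    db += arma::sum(dyb, 0).t();
    arma::mat dcols = dyb * Wm;              // (H*B) x C*k*k
    col2im_block(dx, k, c0, B, dcols);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 8-connected component labelling of a binary raster; labels are assigned
// in scan order (down columns, then across) of each component's
// first-visited pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int nr = p.first + dr, nc = p.second + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && !lab(nr, nc)) {
              lab(nr, nc) = next;
              stack.push_back(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  return lab;
}
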