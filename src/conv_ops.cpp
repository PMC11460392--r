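// Convolution primitives for the residual denoiser: same-size (zero-padded,
// stride-1) 2-D convolutions expressed as im2col + GEMM so the heavy lifting
// runs in BLAS. Weight matrices are (Cin*k*k) x Cout with row index
// c*k*k + dj*k + di (di = kernel row offset, fastest; dj = kernel col
// offset; c = input channel) -- the layout build_denoiser() uses.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static void im2col(const cube& x, int k, mat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  col.zeros(static_cast<uword>(H) * W, static_cast<uword>(C) * k * k);
  uword idx = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++idx) {
        const int si = di - p, sj = dj - p;
        const int r0 = std::max(0, -si), r1 = std::min(H, H - si);
        const int c0 = std::max(0, -sj), c1 = std::min(W, W - sj);
        if (r1 <= r0 || c1 <= c0) continue;
        mat dst(col.colptr(idx), H, W, false, true);
        dst.submat(r0, c0, r1 - 1, c1 - 1) =
          x.slice(c).submat(r0 + si, c0 + sj, r1 - 1 + si, c1 - 1 + sj);
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back onto the image grid.
static cube col2im(const mat& gcol, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  cube gx(H, W, C, fill::zeros);
  uword idx = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++idx) {
        const int si = di - p, sj = dj - p;
        const int r0 = std::max(0, -si), r1 = std::min(H, H - si);
        const int c0 = std::max(0, -sj), c1 = std::min(W, W - sj);
        if (r1 <= r0 || c1 <= c0) continue;
        const mat src(const_cast<double*>(gcol.colptr(idx)), H, W,
                      false, true);
        gx.slice(c).submat(r0 + si, c0 + sj, r1 - 1 + si, c1 - 1 + sj) +=
          src.submat(r0, c0, r1 - 1, c1 - 1);
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& w,
                            const arma::vec& bias, int k) {
  if (w.n_rows != x.n_slices * static_cast<uword>(k) * k)
    Rcpp::stop("weight rows (%d) != Cin*k*k (%d)", (int)w.n_rows,
               (int)(x.n_slices * k * k));
  mat col;
  im2col(x, k, col);
  mat y = col * w;                    // (H*W) x Cout
  y.each_row() += bias.t();
  cube out(x.n_rows, x.n_cols, w.n_cols);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// Gradient of the loss w.r.t. weights, bias and (optionally) the layer
// input, given the upstream gradient gy at the layer output.
// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& x, const arma::cube& gy,
                             const arma::mat& w, int k, bool need_gx) {
  const int H = x.n_rows, W = x.n_cols;
  mat col;
  im2col(x, k, col);
  const mat gym(const_cast<double*>(gy.memptr()),
                static_cast<uword>(H) * W, gy.n_slices, false, true);
  mat gw = col.t() * gym;
  vec gb = sum(gym, 0).t();
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("gw") = gw,
                                      Rcpp::Named("gb") = gb);
  if (need_gx) {
    mat gcol = gym * w.t();
    out["gx"] = col2im(gcol, H, W, x.n_slices, k);
  }
  return out;
}

// Transpose (adjoint) convolution, used by the spectral-norm power
// iteration: maps Cout-channel fields back to Cin channels.
// [[Rcpp::export]]
arma::cube cpp_conv_transpose(const arma::cube& u, const arma::mat& w,
                              int k, int cin) {
  const int H = u.n_rows, W = u.n_cols;
  const mat um(const_cast<double*>(u.memptr()),
               static_cast<uword>(H) * W, u.n_slices, false, true);
  mat gcol = um * w.t();
  return col2im(gcol, H, W, cin, k);
}
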