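// Whole-network kernels for the residual denoiser, single-precision
// internally (the network is trained to ~1e-3 accuracy; float GEMM is
// around twice as fast as double on this workload). The double-precision
// layer primitives in conv_ops.cpp remain the reference implementation
// that unit tests compare against dense-operator oracles.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static void im2col_f(const fcube& x, int k, fmat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  col.zeros(static_cast<uword>(H) * W, static_cast<uword>(C) * k * k);
  uword idx = 0;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di, ++idx) {
        const int si = di - p, sj = dj - p;
        const int r0 = std::max(0, -si), r1 = std::min(H, H - si);
        const int c0 = std::max(0, -sj), c1 = std::min(W, W - sj);
        if (r1 <= r0 || c1 <= c0) continue;
        fmat dst(col.colptr(idx), H, W, false, true);
        dst.submat(r0, c0, r1 - 1, c1 - 1) =
          x.slice(c).submat(r0 + si, c0 + sj, r1 - 1 + si, c1 - 1 + sj);
      }
}

static fcube col2im_f(const fmat& gcol, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  fcube gx(H, W, C, fill::zeros);
  uword idx = 0;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di, ++idx) {
        const int si = di - p, sj = dj - p;
        const int r0 = std::max(0, -si), r1 = std::min(H, H - si);
        const int c0 = std::max(0, -sj), c1 = std::min(W, W - sj);
        if (r1 <= r0 || c1 <= c0) continue;
        const fmat src(const_cast<float*>(gcol.colptr(idx)), H, W,
                       false, true);
        gx.slice(c).submat(r0 + si, c0 + sj, r1 - 1 + si, c1 - 1 + sj) +=
          src.submat(r0, c0, r1 - 1, c1 - 1);
      }
  return gx;
}

static std::vector<fmat> weights_f(const Rcpp::List& Ws) {
  std::vector<fmat> out(Ws.size());
  for (int l = 0; l < Ws.size(); ++l)
    out[l] = conv_to<fmat>::from(Rcpp::as<mat>(Ws[l]));
  return out;
}

static std::vector<fvec> biases_f(const Rcpp::List& bs) {
  std::vector<fvec> out(bs.size());
  for (int l = 0; l < bs.size(); ++l)
    out[l] = conv_to<fvec>::from(Rcpp::as<vec>(bs[l]));
  return out;
}

// Residual (noise) estimate of the full network for one image.
// [[Rcpp::export]]
arma::mat cpp_net_forward(const arma::mat& x, const Rcpp::List& Ws,
                          const Rcpp::List& bs, int k) {
  const int H = x.n_rows, W = x.n_cols, L = Ws.size();
  std::vector<fmat> w = weights_f(Ws);
  std::vector<fvec> b = biases_f(bs);
  fcube h(H, W, 1);
  h.slice(0) = conv_to<fmat>::from(x);
  fmat col;
  for (int l = 0; l < L; ++l) {
    im2col_f(h, k, col);
    fmat y = col * w[l];
    y.each_row() += b[l].t();
    if (l < L - 1) y.transform([](float v) { return v > 0 ? v : 0.0f; });
    h.set_size(H, W, y.n_cols);
    std::memcpy(h.memptr(), y.memptr(), sizeof(float) * y.n_elem);
  }
  return conv_to<mat>::from(h.slice(0));
}

// Full forward + backward over a batch, accumulating weight/bias
// gradients of the summed squared error between net(X) and (X - Y).
// [[Rcpp::export]]
Rcpp::List cpp_net_backward_batch(const Rcpp::List& xs, const Rcpp::List& ys,
                                  const Rcpp::List& Ws, const Rcpp::List& bs,
                                  int k) {
  const int L = Ws.size(), B = xs.size();
  std::vector<fmat> w = weights_f(Ws);
  std::vector<fvec> b = biases_f(bs);
  std::vector<mat> gw(L);
  std::vector<vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gw[l].zeros(w[l].n_rows, w[l].n_cols);
    gb[l].zeros(w[l].n_cols);
  }
  double loss = 0;
  fmat col;
  for (int img = 0; img < B; ++img) {
    const mat xd = Rcpp::as<mat>(xs[img]);
    const mat yd = Rcpp::as<mat>(ys[img]);
    const int H = xd.n_rows, W = xd.n_cols;
    // forward, keeping each layer's input (post-activation) and a ReLU
    // mask of its pre-activation
    std::vector<fcube> inputs(L);
    std::vector<fcube> relu_mask(L);   // for layers 0..L-2
    fcube h(H, W, 1);
    h.slice(0) = conv_to<fmat>::from(xd);
    for (int l = 0; l < L; ++l) {
      inputs[l] = h;
      im2col_f(h, k, col);
      fmat y = col * w[l];
      y.each_row() += b[l].t();
      if (l < L - 1) {
        fmat msk = conv_to<fmat>::from(y > 0.0f);
        y %= msk;
        relu_mask[l].set_size(H, W, y.n_cols);
        std::memcpy(relu_mask[l].memptr(), msk.memptr(),
                    sizeof(float) * msk.n_elem);
      }
      h.set_size(H, W, y.n_cols);
      std::memcpy(h.memptr(), y.memptr(), sizeof(float) * y.n_elem);
    }
    // residual target is the noise field x - y
    fmat diff = h.slice(0) - conv_to<fmat>::from(xd - yd);
    loss += dot(diff, diff);
    fcube g(H, W, 1);
    g.slice(0) = 2.0f * diff;
    for (int l = L - 1; l >= 0; --l) {
      im2col_f(inputs[l], k, col);
      const fmat gym(const_cast<float*>(g.memptr()),
                     static_cast<uword>(H) * W, g.n_slices, false, true);
      gw[l] += conv_to<mat>::from(fmat(col.t() * gym));
      gb[l] += conv_to<vec>::from(fvec(sum(gym, 0).t()));
      if (l > 0) {
        fmat gcol = gym * w[l].t();
        g = col2im_f(gcol, H, W, inputs[l].n_slices, k);
        for (uword s = 0; s < g.n_slices; ++s)
          g.slice(s) %= relu_mask[l - 1].slice(s);
      }
    }
  }
  Rcpp::List gwl(L), gbl(L);
  for (int l = 0; l < L; ++l) {
    gwl[l] = gw[l];
    gbl[l] = gb[l];
  }
  return Rcpp::List::create(Rcpp::Named("gw") = gwl,
                            Rcpp::Named("gb") = gbl,
                            Rcpp::Named("loss") = loss);
}

// Power iteration on one convolution layer's operator at image size
// `size`, run entirely in C++. Returns the norm estimate, the warm-start
// vector and the relative change of the last step.
// [[Rcpp::export]]
Rcpp::List cpp_power_iter(const arma::mat& wd, int cin, int k, int size,
                          int iters, const arma::vec& v0) {
  fmat w = conv_to<fmat>::from(wd);
  const int cout = w.n_cols;
  if ((int)v0.n_elem != size * size * cin)
    Rcpp::stop("v0 must have length size^2 * cin");
  fcube v(size, size, cin);
  std::memcpy(v.memptr(), conv_to<fvec>::from(v0).memptr(),
              sizeof(float) * v.n_elem);
  float nv = norm(vectorise(v), 2);
  if (nv == 0) nv = 1;
  v /= nv;
  fmat col;
  double sigma = 0, sigma_prev = -1;
  for (int it = 0; it < iters; ++it) {
    im2col_f(v, k, col);
    fmat u = col * w;                       // (size^2) x cout
    float nu = norm(vectorise(u), 2);
    if (nu == 0) {
      return Rcpp::List::create(Rcpp::Named("sigma") = 0.0,
                                Rcpp::Named("v") = conv_to<vec>::from(vectorise(v)),
                                Rcpp::Named("delta") = 0.0);
    }
    u /= nu;
    fmat gcol = u * w.t();
    v = col2im_f(gcol, size, size, cin, k);
    sigma_prev = sigma;
    sigma = norm(vectorise(v), 2);
    v /= (float)sigma;
  }
  double delta = sigma_prev > 0 ? std::abs(sigma - sigma_prev) / sigma : 1.0;
  return Rcpp::List::create(Rcpp::Named("sigma") = sigma,
                            Rcpp::Named("v") = conv_to<vec>::from(vectorise(v)),
                            Rcpp::Named("delta") = delta);
}
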