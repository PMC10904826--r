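// Low-level numeric kernels: im2col convolution (forward/backward) and
// inverse-mapping homography warps. Image/feature layout is arma::cube
// (rows = y, cols = x, slices = channels), matching R arrays dim (h, w, c).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// cols: (c_in * kh * kw) x (oh * ow); patch index runs y-fastest over output,
// within a column the unrolling is (channel, ky, kx) with channel fastest.
static mat im2col(const cube& input, int kh, int kw, int stride, int pad) {
  const int h = input.n_rows, w = input.n_cols, c = input.n_slices;
  const int oh = out_size(h, kh, stride, pad);
  const int ow = out_size(w, kw, stride, pad);
  mat cols(c * kh * kw, oh * ow, fill::zeros);
  for (int ox = 0; ox < ow; ++ox) {
    for (int oy = 0; oy < oh; ++oy) {
      const int col = ox * oh + oy;
      const int y0 = oy * stride - pad, x0 = ox * stride - pad;
      for (int kx = 0; kx < kw; ++kx) {
        const int x = x0 + kx;
        if (x < 0 || x >= w) continue;
        for (int ky = 0; ky < kh; ++ky) {
          const int y = y0 + ky;
          if (y < 0 || y >= h) continue;
          for (int ch = 0; ch < c; ++ch)
            cols((kx * kh + ky) * c + ch, col) = input(y, x, ch);
        }
      }
    }
  }
  return cols;
}

static void col2im_acc(const mat& cols, cube& out, int kh, int kw,
                       int stride, int pad) {
  const int h = out.n_rows, w = out.n_cols, c = out.n_slices;
  const int oh = out_size(h, kh, stride, pad);
  const int ow = out_size(w, kw, stride, pad);
  for (int ox = 0; ox < ow; ++ox) {
    for (int oy = 0; oy < oh; ++oy) {
      const int col = ox * oh + oy;
      const int y0 = oy * stride - pad, x0 = ox * stride - pad;
      for (int kx = 0; kx < kw; ++kx) {
        const int x = x0 + kx;
        if (x < 0 || x >= w) continue;
        for (int ky = 0; ky < kh; ++ky) {
          const int y = y0 + ky;
          if (y < 0 || y >= h) continue;
          for (int ch = 0; ch < c; ++ch)
            out(y, x, ch) += cols((kx * kh + ky) * c + ch, col);
        }
      }
    }
  }
}

// weights: (c_out) x (c_in * kh * kw), row-unrolling as in im2col.
// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& input, const arma::mat& weights,
                          const arma::vec& bias, int kh, int kw,
                          int stride, int pad) {
  const int oh = out_size(input.n_rows, kh, stride, pad);
  const int ow = out_size(input.n_cols, kw, stride, pad);
  const int c_out = weights.n_rows;
  mat cols = im2col(input, kh, kw, stride, pad);
  mat res = weights * cols;            // c_out x (oh*ow)
  res.each_col() += bias;
  cube out(oh, ow, c_out);
  for (int ch = 0; ch < c_out; ++ch)
    out.slice(ch) = reshape(res.row(ch), oh, ow);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube& input, const arma::mat& weights,
                           const arma::cube& grad_out, int kh, int kw,
                           int stride, int pad) {
  const int c_out = weights.n_rows;
  const int oh = grad_out.n_rows, ow = grad_out.n_cols;
  mat g(c_out, oh * ow);
  for (int ch = 0; ch < c_out; ++ch)
    g.row(ch) = vectorise(grad_out.slice(ch)).t();
  mat cols = im2col(input, kh, kw, stride, pad);
  mat dW = g * cols.t();
  vec db = sum(g, 1);
  mat dcols = weights.t() * g;
  cube dinput(input.n_rows, input.n_cols, input.n_slices, fill::zeros);
  col2im_acc(dcols, dinput, kh, kw, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dinput") = dinput,
                            Rcpp::Named("dweights") = dW,
                            Rcpp::Named("dbias") = db);
}

// Inverse-mapping warp: for each destination pixel (x, y) (0-based), sample the
// source at Hinv %*% (x, y, 1). Out-of-source pixels take `fill`.
// [[Rcpp::export]]
arma::mat warp_bilinear(const arma::mat& img, const arma::mat& Hinv,
                        double fill) {
  const int h = img.n_rows, w = img.n_cols;
  mat out(h, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      const double dz = Hinv(2,0) * x + Hinv(2,1) * y + Hinv(2,2);
      const double sx = (Hinv(0,0) * x + Hinv(0,1) * y + Hinv(0,2)) / dz;
      const double sy = (Hinv(1,0) * x + Hinv(1,1) * y + Hinv(1,2)) / dz;
      if (sx < 0 || sy < 0 || sx > w - 1 || sy > h - 1) {
        out(y, x) = fill;
        continue;
      }
      const int x0 = std::min((int)std::floor(sx), w - 2);
      const int y0 = std::min((int)std::floor(sy), h - 2);
      const double fx = sx - x0, fy = sy - y0;
      out(y, x) =
        img(y0,     x0) * (1 - fx) * (1 - fy) +
        img(y0,     x0 + 1) * fx * (1 - fy) +
        img(y0 + 1, x0) * (1 - fx) * fy +
        img(y0 + 1, x0 + 1) * fx * fy;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat warp_nearest(const arma::mat& img, const arma::mat& Hinv,
                       double fill) {
  const int h = img.n_rows, w = img.n_cols;
  mat out(h, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      const double dz = Hinv(2,0) * x + Hinv(2,1) * y + Hinv(2,2);
      const double sx = (Hinv(0,0) * x + Hinv(0,1) * y + Hinv(0,2)) / dz;
      const double sy = (Hinv(1,0) * x + Hinv(1,1) * y + Hinv(1,2)) / dz;
      const int xr = (int)std::lround(sx), yr = (int)std::lround(sy);
      out(y, x) = (xr < 0 || yr < 0 || xr >= w || yr >= h) ? fill : img(yr, xr);
    }
  }
  return out;
}
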