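// Minimal BLAS-backed convolutional primitives for the detector.
// Tensors are H x W x C arma::cubes (matching R's array layout); convolution
// is im2col + GEMM. Backward passes mirror the forward definitions exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols(C * kh * kw, Hout * Wout, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = c * kh * kw + j * kh + i;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + j - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = cols.colptr(wo * Hout) + row;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride + i - pad;
            if (hi >= 0 && hi < H)
              dst[(size_t)ho * cols.n_rows] = sl(hi, wi);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = x.slice(c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = c * kh * kw + j * kh + i;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + j - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = cols.colptr(wo * Hout) + row;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride + i - pad;
            if (hi >= 0 && hi < H)
              sl(hi, wi) += src[(size_t)ho * cols.n_rows];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_conv_fw(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                 int kh, int kw, int stride, int pad) {
  const int Hout = (x.n_rows + 2 * pad - kh) / stride + 1;
  const int Wout = (x.n_cols + 2 * pad - kw) / stride + 1;
  arma::mat cols = im2col(x, kh, kw, stride, pad);
  arma::mat out_mat = W * cols;
  out_mat.each_col() += b;
  const int Cout = W.n_rows;
  arma::cube out(Hout, Wout, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(out_mat.row(c), Hout, Wout);
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export]]
List cpp_conv_bw(const arma::cube& dy, const arma::mat& cols, const arma::mat& W,
                 int H, int W_in, int C_in, int kh, int kw, int stride, int pad) {
  const int Cout = dy.n_slices;
  const int n = dy.n_rows * dy.n_cols;
  arma::mat dy_mat(Cout, n);
  for (int c = 0; c < Cout; ++c)
    dy_mat.row(c) = arma::vectorise(dy.slice(c)).t();
  arma::mat dW = dy_mat * cols.t();
  arma::vec db = arma::sum(dy_mat, 1);
  arma::mat dcols = W.t() * dy_mat;
  arma::cube dx = col2im(dcols, H, W_in, C_in, kh, kw, stride, pad);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  arma::cube out(Hout, Wout, C);
  arma::ucube idx(Hout, Wout, C); // 0-based linear index into x
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        double best = -arma::datum::inf;
        arma::uword best_i = 0;
        for (int j = 0; j < k; ++j) {
          const int wi = wo * stride + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int hi = ho * stride + i - pad;
            if (hi < 0 || hi >= H) continue;
            const double v = sl(hi, wi);
            if (v > best) { best = v; best_i = (arma::uword)c * H * W + (arma::uword)wi * H + hi; }
          }
        }
        out(ho, wo, c) = best;
        idx(ho, wo, c) = best_i;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dy, const arma::ucube& idx,
                          int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const arma::uword n = dy.n_elem;
  for (arma::uword t = 0; t < n; ++t) dx(idx(t)) += dy(t);
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        out(2 * h, 2 * w, c) = v;
        out(2 * h + 1, 2 * w, c) = v;
        out(2 * h, 2 * w + 1, c) = v;
        out(2 * h + 1, 2 * w + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        dx(h, w, c) = dy(2 * h, 2 * w, c) + dy(2 * h + 1, 2 * w, c) +
                      dy(2 * h, 2 * w + 1, c) + dy(2 * h + 1, 2 * w + 1, c);
  return dx;
}
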