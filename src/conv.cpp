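// 2-D convolution forward/backward kernels (im2col formulation) used by the
// U-Net generators and PatchGAN discriminators. Single image (H x W x C
// cube), arbitrary kernel size, stride and zero padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int K, int stride, int pad,
                        int Ho, int Wo) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(K * K * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int r = ki + K * kj + K * K * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int col0 = wo * stride + kj - pad;
          if (col0 < 0 || col0 >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int row0 = ho * stride + ki - pad;
            if (row0 < 0 || row0 >= H) continue;
            cols(r, ho + Ho * wo) = x(row0, col0, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_acc(arma::cube& gx, const arma::mat& cols, int K,
                       int stride, int pad, int Ho, int Wo) {
  int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int r = ki + K * kj + K * K * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int col0 = wo * stride + kj - pad;
          if (col0 < 0 || col0 >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int row0 = ho * stride + ki - pad;
            if (row0 < 0 || row0 >= H) continue;
            gx(row0, col0, c) += cols(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int K, int stride, int pad) {
  int H = x.n_rows, W = x.n_cols;
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv input smaller than receptive field");
  if ((int)w.n_cols != K * K * (int)x.n_slices)
    stop("weight shape does not match kernel/input channels");
  arma::mat cols = im2col(x, K, stride, pad, Ho, Wo);
  arma::mat out = w * cols;
  out.each_col() += b;
  arma::cube res(Ho, Wo, w.n_rows);
  for (arma::uword co = 0; co < w.n_rows; ++co)
    res.slice(co) = arma::reshape(out.row(co), Ho, Wo);
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& gout, int K, int stride, int pad) {
  int Ho = gout.n_rows, Wo = gout.n_cols;
  arma::mat G(w.n_rows, Ho * Wo);
  for (arma::uword co = 0; co < w.n_rows; ++co)
    G.row(co) = arma::vectorise(gout.slice(co)).t();
  arma::mat cols = im2col(x, K, stride, pad, Ho, Wo);
  arma::mat gw = G * cols.t();
  arma::vec gb = arma::sum(G, 1);
  arma::mat gcols = w.t() * G;
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_acc(gx, gcols, K, stride, pad, Ho, Wo);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
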