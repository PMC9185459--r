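// Convolution kernels for the encoder-decoder refiner.
//
// Tensors use the package's channels-first layout: an array with
// dim = c(C, H, W, B), column-major, so the linear index of element
// (c, h, w, b) is c + C*(h + H*(w + W*b)) (all zero-based here).
// Convolutions are im2col + BLAS gemm; the patch matrix is returned to R
// so the backward pass can reuse it. Row block t = dx*k + dy of the patch
// matrix holds channel values at spatial offset (dy, dx), matching the
// layout of the weight matrices (Cout x k*k*C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const double* x, int C, int H, int W, int B,
                        int k, int pt, int pl) {
  const int n_cols = H * W * B;
  arma::mat Xcol(k * k * C, n_cols, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const int j = h + H * (w + W * b);
        double* col = Xcol.colptr(j);
        for (int dx = 0; dx < k; ++dx) {
          const int sw = w + dx - pl;
          if (sw < 0 || sw >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int sh = h + dy - pt;
            if (sh < 0 || sh >= H) continue;
            const double* src = x + (size_t)C * (sh + (size_t)H * (sw + (size_t)W * b));
            double* dst = col + (dx * k + dy) * C;
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
List conv_fw_cpp(NumericVector X, const arma::mat& W, const arma::vec& b,
                 int k, int pt, int pl) {
  IntegerVector d = X.attr("dim");
  const int C = d[0], H = d[1], Wd = d[2], B = d[3];
  arma::mat Xcol = im2col(REAL(X), C, H, Wd, B, k, pt, pl);
  arma::mat Y = W * Xcol;
  Y.each_col() += b;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create((int)W.n_rows, H, Wd, B);
  return List::create(_["out"] = out, _["Xcol"] = Xcol);
}

// [[Rcpp::export]]
List conv_bw_cpp(NumericVector dY, const arma::mat& W, const arma::mat& Xcol,
                 IntegerVector in_dim, int k, int pt, int pl) {
  const int C = in_dim[0], H = in_dim[1], Wd = in_dim[2], B = in_dim[3];
  IntegerVector dod = dY.attr("dim");
  const int Cout = dod[0];
  arma::mat dYm(REAL(dY), Cout, (size_t)H * Wd * B, false, true);
  arma::mat dW = dYm * Xcol.t();
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dXcol = W.t() * dYm;

  NumericVector dX((size_t)C * H * Wd * B);
  double* dx = REAL(dX);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < Wd; ++w) {
      for (int h = 0; h < H; ++h) {
        const int j = h + H * (w + Wd * b);
        const double* col = dXcol.colptr(j);
        for (int dxo = 0; dxo < k; ++dxo) {
          const int sw = w + dxo - pl;
          if (sw < 0 || sw >= Wd) continue;
          for (int dyo = 0; dyo < k; ++dyo) {
            const int sh = h + dyo - pt;
            if (sh < 0 || sh >= H) continue;
            double* dst = dx + (size_t)C * (sh + (size_t)H * (sw + (size_t)Wd * b));
            const double* src = col + (dxo * k + dyo) * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(C, H, Wd, B);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
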