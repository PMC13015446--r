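// 3x3x3 same-padded 3D convolution primitives used by the MU-Net denoiser.
// Strategy: per z-slice im2col into a (27*Cin x X*Y) patch matrix, then a
// single GEMM against the reshaped weight matrix. The weight matrix layout
// matches the column-major flattening of an R array with dim
// c(3, 3, 3, Cin, Cout): row index = dx + 3*(dy + 3*(dz + 3*ci)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_slice(const double* in, int X, int Y, int Z, int Ci,
                         int z0, arma::mat& P) {
  P.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dz = 0; dz < 3; ++dz) {
      int z = z0 + dz - 1;
      if (z < 0 || z >= Z) continue;
      for (int dy = 0; dy < 3; ++dy) {
        for (int dx = 0; dx < 3; ++dx) {
          int row = dx + 3 * (dy + 3 * (dz + 3 * ci));
          // source x index = x + dx - 1, valid x range below
          int x_lo = std::max(0, 1 - dx);
          int x_hi = std::min(X, X + 1 - dx);
          for (int y = 0; y < Y; ++y) {
            int yy = y + dy - 1;
            if (yy < 0 || yy >= Y) continue;
            const double* src = in + (size_t)X * (yy + (size_t)Y * (z + (size_t)Z * ci));
            for (int x = x_lo; x < x_hi; ++x)
              P(row, x + X * y) = src[x + dx - 1];
          }
        }
      }
    }
  }
}

// input: numeric array dim (X,Y,Z,Ci); W: matrix (27*Ci x Co); bias: length Co
// returns array dim (X,Y,Z,Co)
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector input, NumericMatrix W,
                         NumericVector bias) {
  IntegerVector d = input.attr("dim");
  if (d.size() != 4) stop("input must be a 4D array (X,Y,Z,C)");
  int X = d[0], Y = d[1], Z = d[2], Ci = d[3];
  if (W.nrow() != 27 * Ci) stop("weight rows do not match 27*Cin");
  int Co = W.ncol();
  if (bias.size() != Co) stop("bias length does not match Cout");
  NumericVector out(Rcpp::no_init((size_t)X * Y * Z * Co));
  out.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  arma::mat Wm(W.begin(), 27 * Ci, Co, false, true);
  arma::mat P(27 * Ci, (size_t)X * Y);
  arma::mat O(Co, (size_t)X * Y);
  const double* in = input.begin();
  double* op = out.begin();
  for (int z0 = 0; z0 < Z; ++z0) {
    im2col_slice(in, X, Y, Z, Ci, z0, P);
    O = Wm.t() * P;
    for (int co = 0; co < Co; ++co) {
      double b = bias[co];
      double* dst = op + (size_t)X * Y * (z0 + (size_t)Z * co);
      const double* src = O.memptr() + co; // row co of O, stride Co
      for (size_t i = 0; i < (size_t)X * Y; ++i)
        dst[i] = src[i * Co] + b;
    }
  }
  return out;
}

// Gradient of the loss w.r.t. weights and bias given the conv input and the
// gradient at the conv output. Returns list(gw = (27*Ci x Co), gb = Co).
// [[Rcpp::export]]
List conv3d_gradw(NumericVector input, NumericVector grad_out) {
  IntegerVector d = input.attr("dim");
  IntegerVector dg = grad_out.attr("dim");
  if (d.size() != 4 || dg.size() != 4) stop("inputs must be 4D arrays");
  int X = d[0], Y = d[1], Z = d[2], Ci = d[3];
  int Co = dg[3];
  if (dg[0] != X || dg[1] != Y || dg[2] != Z)
    stop("grad_out spatial shape does not match input");
  arma::mat GW(27 * Ci, Co, arma::fill::zeros);
  arma::vec GB(Co, arma::fill::zeros);
  arma::mat P(27 * Ci, (size_t)X * Y);
  arma::mat G(Co, (size_t)X * Y);
  const double* in = input.begin();
  const double* gp = grad_out.begin();
  for (int z0 = 0; z0 < Z; ++z0) {
    im2col_slice(in, X, Y, Z, Ci, z0, P);
    for (int co = 0; co < Co; ++co) {
      const double* src = gp + (size_t)X * Y * (z0 + (size_t)Z * co);
      double* dst = G.memptr() + co;
      double acc = 0.0;
      for (size_t i = 0; i < (size_t)X * Y; ++i) {
        dst[i * Co] = src[i];
        acc += src[i];
      }
      GB[co] += acc;
    }
    GW += P * G.t();
  }
  return List::create(_["gw"] = wrap(GW), _["gb"] = wrap(GB));
}
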