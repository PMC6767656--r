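// 3x3 same-padding convolution layers on (H, W, B, C) arrays.
// im2col gathers run over contiguous h-columns; channel contractions are
// single BLAS GEMMs through Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather the 9 shifted 3x3 neighbourhood views of x into an (H*W*B) x (9*C)
// matrix; offset order is dj-major, di-minor, matching the kernel reshape
static arma::mat im2col3(const double* x, int H, int W, int B, int C) {
  arma::mat XC(static_cast<size_t>(H) * W * B, 9 * C, arma::fill::zeros);
  for (int dj = 0; dj < 3; ++dj) {
    for (int di = 0; di < 3; ++di) {
      const int s = dj * 3 + di;
      for (int c = 0; c < C; ++c) {
        double* dst0 = XC.colptr(s * C + c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int wsrc = w + dj - 1;
            if (wsrc < 0 || wsrc >= W) continue;
            const double* src = x + ((static_cast<long>(c) * B + b) * W + wsrc) * H;
            double* dst = dst0 + (static_cast<long>(b) * W + w) * H;
            const int h0 = (di == 0) ? 1 : 0;          // skip top pad row
            const int h1 = (di == 2) ? H - 1 : H;      // skip bottom pad row
            for (int h = h0; h < h1; ++h) dst[h] = src[h + di - 1];
          }
        }
      }
    }
  }
  return XC;
}

// kernel (3, 3, Cin, Cout) -> (9*Cin) x Cout, offset order as in im2col3
static arma::mat kernel_mat(const NumericVector& K, int Cin, int Cout) {
  arma::mat Km(9 * Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          Km((dj * 3 + di) * Cin + ci, co) =
            K[di + 3 * (dj + 3 * (ci + static_cast<long>(Cin) * co))];
  return Km;
}

// [[Rcpp::export]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericVector K, NumericVector b) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], B = d[2], Cin = d[3];
  IntegerVector dk = K.attr("dim");
  int Cout = dk[3];
  arma::mat XC = im2col3(x.begin(), H, W, B, Cin);
  arma::mat Km = kernel_mat(K, Cin, Cout);
  arma::mat out = XC * Km;
  out.each_row() += arma::rowvec(b.begin(), Cout);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return res;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericVector x, NumericVector K, NumericVector dout) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], B = d[2], Cin = d[3];
  IntegerVector dk = K.attr("dim");
  int Cout = dk[3];
  const long HWB = static_cast<long>(H) * W * B;
  arma::mat XC = im2col3(x.begin(), H, W, B, Cin);
  arma::mat dM(dout.begin(), HWB, Cout, false, true);
  arma::mat dKm = XC.t() * dM;                     // (9*Cin) x Cout
  NumericVector dK(9 * Cin * Cout);
  dK.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          dK[di + 3 * (dj + 3 * (ci + static_cast<long>(Cin) * co))] =
            dKm((dj * 3 + di) * Cin + ci, co);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(dM.col(co));
  // dx = same-padding correlation of dout with the flipped kernel
  arma::mat DC = im2col3(dout.begin(), H, W, B, Cout);
  arma::mat Kf(9 * Cout, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          Kf((dj * 3 + di) * Cout + co, ci) =
            K[(2 - di) + 3 * ((2 - dj) + 3 * (ci + static_cast<long>(Cin) * co))];
  arma::mat dxm = DC * Kf;
  NumericVector dx(dxm.begin(), dxm.end());
  dx.attr("dim") = IntegerVector::create(H, W, B, Cin);
  return List::create(Named("dx") = dx, Named("dK") = dK, Named("db") = db);
}
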