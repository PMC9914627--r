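// Stride-1, same-padding 2-D convolution over (H, W, batch, channel)
// arrays via im2col + BLAS GEMM. The patch matrix is rebuilt (cheaply)
// in the backward pass instead of being cached, keeping the R-side
// memory footprint at one tensor per op.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the im2col matrix P (HWB x k*k*Cin); row r = h + H*(w + W*b),
// column = (dx*k + dy)*Cin + ci, matching column-major flattening on the
// R side.
static void im2col(const double* x, arma::mat& P, int H, int W, int B,
                   int Cin, int k) {
  const int p = (k - 1) / 2;
  const long HW = (long)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = (dx * k + dy) * Cin + ci;
        double* dst = P.colptr(col);
        const int h0 = std::max(0, p - dy);
        const int h1 = std::min(H, H + p - dy); // rows [h0, h1)
        for (int b = 0; b < B; ++b) {
          const double* xb = x + HW * (b + (long)B * ci);
          for (int wo = 0; wo < W; ++wo) {
            const int ws = wo + dx - p;
            double* drow = dst + (long)H * (wo + (long)W * b);
            if (ws < 0 || ws >= W) {
              std::fill(drow, drow + H, 0.0);
              continue;
            }
            const double* src = xb + (long)H * ws + (dy - p);
            if (h0 > 0) std::fill(drow, drow + h0, 0.0);
            for (int h = h0; h < h1; ++h) drow[h] = src[h];
            if (h1 < H) std::fill(drow + h1, drow + H, 0.0);
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add the patch-gradient matrix back to dx.
static void col2im(const arma::mat& dP, double* dx, int H, int W, int B,
                   int Cin, int k) {
  const int p = (k - 1) / 2;
  const long HW = (long)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dx_ = 0; dx_ < k; ++dx_) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = (dx_ * k + dy) * Cin + ci;
        const double* src = dP.colptr(col);
        const int h0 = std::max(0, p - dy);
        const int h1 = std::min(H, H + p - dy);
        for (int b = 0; b < B; ++b) {
          double* xb = dx + HW * (b + (long)B * ci);
          for (int wo = 0; wo < W; ++wo) {
            const int ws = wo + dx_ - p;
            if (ws < 0 || ws >= W) continue;
            const double* srow = src + (long)H * (wo + (long)W * b);
            double* drow = xb + (long)H * ws + (dy - p);
            for (int h = h0; h < h1; ++h) drow[h] += srow[h];
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& w, int k, int Cin,
                               int Cout) {
  arma::mat Wm(k * k * Cin, Cout);
  const double* wp = w.begin(); // (k, k, Cin, Cout) column-major
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dx = 0; dx < k; ++dx) {
        for (int dy = 0; dy < k; ++dy) {
          Wm((dx * k + dy) * Cin + ci, co) =
            wp[dy + k * (dx + k * (ci + (long)Cin * co))];
        }
      }
    }
  }
  return Wm;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[3];
  const long HWB = (long)H * W * B;
  arma::mat P(HWB, (long)k * k * Cin);
  im2col(x.begin(), P, H, W, B, Cin, k);
  arma::mat out = P * weight_matrix(w, k, Cin, Cout);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
  }
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector grad, NumericVector x, NumericVector w,
                bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[3];
  const long HWB = (long)H * W * B;
  arma::mat P(HWB, (long)k * k * Cin);
  im2col(x.begin(), P, H, W, B, Cin, k);
  arma::mat G(grad.begin(), HWB, Cout, false, true);
  arma::mat dWm = P.t() * G;
  arma::mat Wm = weight_matrix(w, k, Cin, Cout);
  arma::mat dP = G * Wm.t();
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  col2im(dP, dx.begin(), H, W, B, Cin, k);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  double* dwp = dw.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dx_ = 0; dx_ < k; ++dx_) {
        for (int dy = 0; dy < k; ++dy) {
          dwp[dy + k * (dx_ + k * (ci + (long)Cin * co))] =
            dWm((dx_ * k + dy) * Cin + ci, co);
        }
      }
    }
  }
  List out = List::create(Named("dx") = dx, Named("dw") = dw);
  if (has_bias) {
    arma::rowvec db = arma::sum(G, 0);
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}
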