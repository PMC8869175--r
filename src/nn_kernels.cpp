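// Low-level network kernels. Feature maps are R arrays in (H, W, C, N)
// column-major layout; convolution weights are (kh, kw, Cin, Cout).
// Stride is fixed at 1: resolution changes go through the explicit
// pooling / upsampling kernels below, mirroring the residual block design.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C,
                               int kh, int kw, int pad, int Ho, int Wo) {
  arma::mat col(kh * kw * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col.colptr(ho + Ho * wo);
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          int wi = wo - pad + dw;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho - pad + dh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[hi + H * (wi + W * c)];
            dst[dh + kh * (dw + kw * c)] = v;
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_add(double* gx, const arma::mat& dcol,
                              int H, int W, int C, int kh, int kw,
                              int pad, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = dcol.colptr(ho + Ho * wo);
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          int wi = wo - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho - pad + dh;
            if (hi < 0 || hi >= H) continue;
            gx[hi + H * (wi + W * c)] += src[dh + kh * (dw + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cs_conv2d_fwd(NumericVector x, NumericVector w,
                            NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: channel mismatch");
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output size would be non-positive");
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector y(Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, pad, Ho, Wo);
    arma::mat yn(y.begin() + (R_xlen_t)n * Ho * Wo * Co, Ho * Wo, Co, false, true);
    yn = col.t() * Wm;
    yn.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List cs_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  int Ho = gd[0], Wo = gd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  arma::mat gWm(gw.begin(), kh * kw * Ci, Co, false, true);
  arma::vec gbv(gb.begin(), Co, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, pad, Ho, Wo);
    arma::mat gyn(const_cast<double*>(gy.begin()) + (R_xlen_t)n * Ho * Wo * Co,
                  Ho * Wo, Co, false, true);
    gWm += col * gyn;
    gbv += arma::sum(gyn, 0).t();
    arma::mat dcol = Wm * gyn.t();
    col2im_add(gx.begin() + (R_xlen_t)n * H * W * C, dcol, H, W, C, kh, kw, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cs_avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("avgpool2: spatial size must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xp = px + cn * H * W;
    double* yp = py + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yp[ho + Ho * wo] = 0.25 * (xp[2 * ho + H * (2 * wo)] + xp[2 * ho + 1 + H * (2 * wo)] +
                                   xp[2 * ho + H * (2 * wo + 1)] + xp[2 * ho + 1 + H * (2 * wo + 1)]);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cs_avgpool2_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  int H = Ho * 2, W = Wo * 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* gp = pg + cn * Ho * Wo;
    double* xp = px + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double v = 0.25 * gp[ho + Ho * wo];
        xp[2 * ho + H * (2 * wo)] += v;
        xp[2 * ho + 1 + H * (2 * wo)] += v;
        xp[2 * ho + H * (2 * wo + 1)] += v;
        xp[2 * ho + 1 + H * (2 * wo + 1)] += v;
      }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cs_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H * 2, Wo = W * 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xp = px + cn * H * W;
    double* yp = py + cn * Ho * Wo;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xp[h + H * w];
        yp[2 * h + Ho * (2 * w)] = v;
        yp[2 * h + 1 + Ho * (2 * w)] = v;
        yp[2 * h + Ho * (2 * w + 1)] = v;
        yp[2 * h + 1 + Ho * (2 * w + 1)] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cs_upsample2_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* gp = pg + cn * Ho * Wo;
    double* xp = px + cn * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        xp[h + H * w] = gp[2 * h + Ho * (2 * w)] + gp[2 * h + 1 + Ho * (2 * w)] +
                        gp[2 * h + Ho * (2 * w + 1)] + gp[2 * h + 1 + Ho * (2 * w + 1)];
  }
  return gx;
}
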