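// Convolution, pooling and upsampling kernels for the training engine.
//
// Feature maps are numeric arrays with dim = c(H, W, C, N) (column-major,
// H fastest).  Convolution weights have dim = c(kh, kw, cin_per_group, cout).
// All convolutions are stride 1; spatial downsampling is done by pooling.
//
// Three execution paths:
//   * 1x1 convolutions (the dominant FLOP share here) -> one dgemm per sample,
//     no im2col: X_n viewed as (H*W, C), Y_n = X_n * W.
//   * depthwise convolutions (groups == cin == cout) -> direct shifted-slab
//     accumulation, no intermediate buffer.
//   * everything else (standard / dilated / 4-group 3x3) -> im2col + dgemm.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int pad, int dil) {
  return in + 2 * pad - dil * (k - 1);
}

// ---------------------------------------------------------------------------
// im2col helpers (per sample, per group)
// ---------------------------------------------------------------------------

static void im2col(const double* x, int H, int W, int cin_pg, int c0,
                   int C, int kh, int kw, int pad, int dil,
                   int Ho, int Wo, arma::mat& A) {
  // A: (Ho*Wo) x (kh*kw*cin_pg); column r = ki + kh*kj + kh*kw*ci holds the
  // shifted input plane, so both the fill and the GEMM read contiguously
  const int HW = H * W;
  for (int ci = 0; ci < cin_pg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * kj + kh * kw * ci;
        double* acol = A.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo - pad + kj * dil;
          double* adst = acol + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(adst, adst + Ho, 0.0);
            continue;
          }
          const int h0 = std::min(std::max(0, pad - ki * dil), Ho);
          const int h1 = std::max(std::min(Ho, H + pad - ki * dil), h0);
          const double* xcol = xc + (size_t)wi * H - pad + ki * dil;
          if (h0 > 0) std::fill(adst, adst + h0, 0.0);
          for (int ho = h0; ho < h1; ++ho) adst[ho] = xcol[ho];
          if (h1 < Ho) std::fill(adst + h1, adst + Ho, 0.0);
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& A, double* gx, int H, int W,
                       int cin_pg, int c0, int C, int kh, int kw,
                       int pad, int dil, int Ho, int Wo) {
  const int HW = H * W;
  for (int ci = 0; ci < cin_pg; ++ci) {
    double* gxc = gx + (size_t)(c0 + ci) * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * kj + kh * kw * ci;
        const double* acol = A.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const int h0 = std::min(std::max(0, pad - ki * dil), Ho);
          const int h1 = std::max(std::min(Ho, H + pad - ki * dil), h0);
          const double* asrc = acol + (size_t)wo * Ho;
          double* gxcol = gxc + (size_t)wi * H - pad + ki * dil;
          for (int ho = h0; ho < h1; ++ho) gxcol[ho] += asrc[ho];
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// depthwise direct path
// ---------------------------------------------------------------------------

static void dw_fwd(const double* x, double* y, int H, int W, int C,
                   int kh, int kw, int pad, int dil, int Ho, int Wo,
                   const double* wgt) {
  // weight dim (kh, kw, 1, C)
  const int HW = H * W, HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    double* yc = y + (size_t)c * HWo;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double wv = wgt[ki + kh * kj + kh * kw * c];
        if (wv == 0.0) continue;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const int h0 = std::min(std::max(0, pad - ki * dil), Ho);
          const int h1 = std::max(std::min(Ho, H + pad - ki * dil), h0);
          const double* xcol = xc + (size_t)wi * H - pad + ki * dil;
          double* ycol = yc + (size_t)wo * Ho;
          for (int ho = h0; ho < h1; ++ho) ycol[ho] += wv * xcol[ho];
        }
      }
    }
  }
}

static void dw_bwd_input(const double* gy, double* gx, int H, int W, int C,
                         int kh, int kw, int pad, int dil, int Ho, int Wo,
                         const double* wgt) {
  const int HW = H * W, HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* gyc = gy + (size_t)c * HWo;
    double* gxc = gx + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double wv = wgt[ki + kh * kj + kh * kw * c];
        if (wv == 0.0) continue;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const int h0 = std::min(std::max(0, pad - ki * dil), Ho);
          const int h1 = std::max(std::min(Ho, H + pad - ki * dil), h0);
          const double* gycol = gyc + (size_t)wo * Ho;
          double* gxcol = gxc + (size_t)wi * H - pad + ki * dil;
          for (int ho = h0; ho < h1; ++ho) gxcol[ho] += wv * gycol[ho];
        }
      }
    }
  }
}

static void dw_bwd_weight(const double* x, const double* gy, double* gw,
                          int H, int W, int C, int kh, int kw, int pad,
                          int dil, int Ho, int Wo) {
  const int HW = H * W, HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    const double* gyc = gy + (size_t)c * HWo;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double acc = 0.0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const int h0 = std::min(std::max(0, pad - ki * dil), Ho);
          const int h1 = std::max(std::min(Ho, H + pad - ki * dil), h0);
          const double* xcol = xc + (size_t)wi * H - pad + ki * dil;
          const double* gycol = gyc + (size_t)wo * Ho;
          for (int ho = h0; ho < h1; ++ho) acc += xcol[ho] * gycol[ho];
        }
        gw[ki + kh * kj + kh * kw * c] += acc;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// exported conv ops
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_pg = wd[2], cout = wd[3];
  if (C != cin_pg * groups) stop("conv2d: input channels do not match weight");
  if (cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  const int cout_pg = cout / groups;
  const int Ho = out_size(H, kh, pad, dil), Wo = out_size(W, kw, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  NumericVector y((R_xlen_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const double* xp = x.begin(); double* yp = y.begin();
  const size_t xstr = (size_t)H * W * C, ystr = (size_t)Ho * Wo * cout;

  if (kh == 1 && kw == 1 && groups == 1) {
    arma::mat Wm(const_cast<double*>(w.begin()), cin_pg, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(xp) + n * xstr, (size_t)H * W, C, false, true);
      arma::mat Yn(yp + n * ystr, (size_t)Ho * Wo, cout, false, true);
      Yn = Xn * Wm;
    }
    return y;
  }
  if (cin_pg == 1 && cout_pg == 1 && groups == C && cout == C) {
    for (int n = 0; n < N; ++n)
      dw_fwd(xp + n * xstr, yp + n * ystr, H, W, C, kh, kw, pad, dil, Ho, Wo,
             w.begin());
    return y;
  }
  const int rows = kh * kw * cin_pg;
  arma::mat A((size_t)Ho * Wo, rows);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp + n * xstr, H, W, cin_pg, g * cin_pg, C, kh, kw, pad, dil,
             Ho, Wo, A);
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * rows * cout_pg,
                   rows, cout_pg, false, true);
      arma::mat Yg(yp + n * ystr + (size_t)g * cout_pg * Ho * Wo,
                   (size_t)Ho * Wo, cout_pg, false, true);
      Yg = A * Wg;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_input(NumericVector gy, NumericVector w,
                                   IntegerVector xdim, int pad, int dil,
                                   int groups) {
  IntegerVector yd = gy.attr("dim"), wd = w.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = yd[0], Wo = yd[1], cout = yd[2];
  const int kh = wd[0], kw = wd[1], cin_pg = wd[2];
  const int cout_pg = cout / groups;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double* gyp = gy.begin(); double* gxp = gx.begin();
  const size_t xstr = (size_t)H * W * C, ystr = (size_t)Ho * Wo * cout;

  if (kh == 1 && kw == 1 && groups == 1) {
    arma::mat Wm(const_cast<double*>(w.begin()), cin_pg, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Gy(const_cast<double*>(gyp) + n * ystr, (size_t)Ho * Wo, cout, false, true);
      arma::mat Gx(gxp + n * xstr, (size_t)H * W, C, false, true);
      Gx = Gy * Wm.t();
    }
    return gx;
  }
  if (cin_pg == 1 && cout_pg == 1 && groups == C && cout == C) {
    for (int n = 0; n < N; ++n)
      dw_bwd_input(gyp + n * ystr, gxp + n * xstr, H, W, C, kh, kw, pad, dil,
                   Ho, Wo, w.begin());
    return gx;
  }
  const int rows = kh * kw * cin_pg;
  arma::mat A((size_t)Ho * Wo, rows);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * rows * cout_pg,
                   rows, cout_pg, false, true);
      arma::mat Gy(const_cast<double*>(gyp) + n * ystr + (size_t)g * cout_pg * Ho * Wo,
                   (size_t)Ho * Wo, cout_pg, false, true);
      A = Gy * Wg.t();
      col2im_add(A, gxp + n * xstr, H, W, cin_pg, g * cin_pg, C, kh, kw,
                 pad, dil, Ho, Wo);
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_weight(NumericVector x, NumericVector gy,
                                    IntegerVector wdim, int pad, int dil,
                                    int groups) {
  IntegerVector xd = x.attr("dim"), yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], cout = yd[2];
  const int kh = wdim[0], kw = wdim[1], cin_pg = wdim[2];
  const int cout_pg = cout / groups;
  NumericVector gw((R_xlen_t)kh * kw * cin_pg * cout);
  gw.attr("dim") = wdim;
  const double* xp = x.begin(); const double* gyp = gy.begin();
  const size_t xstr = (size_t)H * W * C, ystr = (size_t)Ho * Wo * cout;

  if (kh == 1 && kw == 1 && groups == 1) {
    arma::mat Gw(gw.begin(), cin_pg, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(xp) + n * xstr, (size_t)H * W, C, false, true);
      arma::mat Gy(const_cast<double*>(gyp) + n * ystr, (size_t)Ho * Wo, cout, false, true);
      Gw += Xn.t() * Gy;
    }
    return gw;
  }
  if (cin_pg == 1 && cout_pg == 1 && groups == C && cout == C) {
    for (int n = 0; n < N; ++n)
      dw_bwd_weight(xp + n * xstr, gyp + n * ystr, gw.begin(), H, W, C,
                    kh, kw, pad, dil, Ho, Wo);
    return gw;
  }
  const int rows = kh * kw * cin_pg;
  arma::mat A((size_t)Ho * Wo, rows);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp + n * xstr, H, W, cin_pg, g * cin_pg, C, kh, kw, pad, dil,
             Ho, Wo, A);
      arma::mat Gy(const_cast<double*>(gyp) + n * ystr + (size_t)g * cout_pg * Ho * Wo,
                   (size_t)Ho * Wo, cout_pg, false, true);
      arma::mat Gw(gw.begin() + (size_t)g * rows * cout_pg, rows, cout_pg,
                   false, true);
      Gw += A.t() * Gy;
    }
  }
  return gw;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin(); double* yp = y.begin(); int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          size_t best = base + (size_t)(2 * wo) * H + 2 * ho;
          double bv = xp[best];
          const size_t cand[3] = { best + 1, best + H, best + H + 1 };
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          yp[o] = bv;
          ip[o] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* gxp = gx.begin();
  const double* gyp = gy.begin(); const int* ip = idx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ip[i]] += gyp[i];
  return gx;
}

// ---------------------------------------------------------------------------
// bilinear x2 upsampling (align_corners = FALSE)
// ---------------------------------------------------------------------------

static void up2_coeff(int Ho, int H, std::vector<int>& i0, std::vector<int>& i1,
                      std::vector<double>& a) {
  i0.resize(Ho); i1.resize(Ho); a.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, H - 1);
    i0[o] = lo; i1[o] = hi; a[o] = s - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0, h1, w0, w1; std::vector<double> ah, aw;
  up2_coeff(Ho, H, h0, h1, ah);
  up2_coeff(Wo, W, w0, w1, aw);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int nc = 0; nc < N * C; ++nc) {
    const double* xs = xp + (size_t)nc * H * W;
    double* ys = yp + (size_t)nc * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = xs + (size_t)w0[wo] * H;
      const double* c1 = xs + (size_t)w1[wo] * H;
      const double bw = aw[wo];
      double* yc = ys + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const double bh = ah[ho];
        const double top = c0[h0[ho]] * (1 - bh) + c0[h1[ho]] * bh;
        const double bot = c1[h0[ho]] * (1 - bh) + c1[h1[ho]] * bh;
        yc[ho] = top * (1 - bw) + bot * bw;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  std::vector<int> h0, h1, w0, w1; std::vector<double> ah, aw;
  up2_coeff(Ho, H, h0, h1, ah);
  up2_coeff(Wo, W, w0, w1, aw);
  const double* gyp = gy.begin(); double* gxp = gx.begin();
  for (int nc = 0; nc < N * C; ++nc) {
    const double* gys = gyp + (size_t)nc * Ho * Wo;
    double* gxs = gxp + (size_t)nc * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      double* c0 = gxs + (size_t)w0[wo] * H;
      double* c1 = gxs + (size_t)w1[wo] * H;
      const double bw = aw[wo];
      const double* gyc = gys + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const double bh = ah[ho];
        const double g = gyc[ho];
        c0[h0[ho]] += g * (1 - bh) * (1 - bw);
        c0[h1[ho]] += g * bh * (1 - bw);
        c1[h0[ho]] += g * (1 - bh) * bw;
        c1[h1[ho]] += g * bh * bw;
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// per-channel helpers for batch normalization and bias
// ---------------------------------------------------------------------------

// y[., c, .] = x[., c, .] * s[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector s,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)HW * C * N);
  y.attr("dim") = xd;
  const double* xp = x.begin(); double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double sc = s[c], bc = b[c];
      const size_t off = ((size_t)n * C + c) * HW;
      for (int i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * sc + bc;
    }
  }
  return y;
}

// per-channel sums of x (and of x*y when y is given)
// [[Rcpp::export]]
NumericVector cpp_chan_sum(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector out(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      double acc = 0.0;
      for (int i = 0; i < HW; ++i) acc += xp[off + i];
      out[c] += acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chan_dot(NumericVector x, NumericVector y) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector out(C);
  const double* xp = x.begin(); const double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      double acc = 0.0;
      for (int i = 0; i < HW; ++i) acc += xp[off + i] * yp[off + i];
      out[c] += acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// grouped spatial shift (zero fill); disp: 8 x 2 integer matrix (dy, dx)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_shift(NumericVector x, IntegerMatrix disp) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = xd;
  const double* xp = x.begin(); double* yp = y.begin();
  const int base = C / 8;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const int gi = c / std::max(base, 1);
      int dy = 0, dx = 0;
      if (base > 0 && gi < 8 && c < 8 * base) {
        dy = disp(gi, 0); dx = disp(gi, 1);
      }
      for (int ws = 0; ws < W; ++ws) {
        const int wt = ws + dx;
        if (wt < 0 || wt >= W) continue;
        const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
        const double* src = xp + off + (size_t)ws * H;
        double* dst = yp + off + (size_t)wt * H + dy;
        for (int hs = h0; hs < h1; ++hs) dst[hs] = src[hs];
      }
    }
  }
  return y;
}

// ---------------------------------------------------------------------------
// ReLU
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// gradient through ReLU, using the forward OUTPUT as the mask
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector gy, NumericVector y) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* gp = gy.begin(); const double* yp = y.begin();
  double* op = gx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : 0;
  return gx;
}

// y[., c, .] = max(x[., c, .] * s[c] + b[c], 0): batch-norm + ReLU fused
// [[Rcpp::export]]
NumericVector cpp_chan_affine_relu(NumericVector x, NumericVector s,
                                   NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)HW * C * N);
  y.attr("dim") = xd;
  const double* xp = x.begin(); double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double sc = s[c], bc = b[c];
      const size_t off = ((size_t)n * C + c) * HW;
      for (int i = 0; i < HW; ++i) {
        const double v = xp[off + i] * sc + bc;
        yp[off + i] = v > 0 ? v : 0;
      }
    }
  }
  return y;
}
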