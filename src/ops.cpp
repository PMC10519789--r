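// Dense and depthwise 2-D convolution kernels plus 2x2-style max pooling,
// operating on column-major arrays laid out (H, W, C, N).  Convolutions use
// im2col + GEMM; backward passes return input/weight/bias gradients.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// col layout: rows indexed (kh fastest, then kw, then c), cols (ho fastest, then wo)
static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int stride, int pt, int pl,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = c * KH * KW + kw * KH + kh;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pl;
          double* dst = col.memptr() + (size_t)col.n_rows * (size_t)Wo * 0; // silence
          (void)dst;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pt;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) v = xc[hi + (size_t)H * wi];
            col(r, wo * Ho + ho) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int KH, int KW, int stride, int pt, int pl,
                       int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = c * KH * KW + kw * KH + kh;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pl;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pt;
            if (hi < 0 || hi >= H) continue;
            gc[hi + (size_t)H * wi] += col(r, wo * Ho + ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                             int stride, int pt, int pl, int Ho, int Wo) {
  int dx[4]; get_dims4(x, dx);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  int KH = dw[0], KW = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)KH * KW * Cin, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col((size_t)KH * KW * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pt, pl, Ho, Wo, col);
    arma::mat yn(y.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    yn = col.t() * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; ++co) yn.col(co) += b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pt, int pl, bool need_gx, bool has_bias) {
  int dx[4]; get_dims4(x, dx);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  int KH = dw[0], KW = dw[1], Cout = dw[3];
  IntegerVector dg = gy.attr("dim");
  int Ho = dg[0], Wo = dg[1];
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)KH * KW * C, Cout, false, true);
  NumericVector gw((size_t)KH * KW * C * Cout);
  gw.attr("dim") = IntegerVector::create(KH, KW, C, Cout);
  arma::mat Gw(gw.begin(), (size_t)KH * KW * C, Cout, false, true);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat col((size_t)KH * KW * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pt, pl, Ho, Wo, col);
    arma::mat Gn(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    Gw += col * Gn;
    if (has_bias) for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gn.col(co));
    if (need_gx) {
      arma::mat gcol = Wm * Gn.t();
      col2im_add(gcol, H, W, C, KH, KW, stride, pt, pl, Ho, Wo,
                 gx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                               int stride, int pt, int pl, int Ho, int Wo) {
  int dx[4]; get_dims4(x, dx);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  int KH = dw[0], KW = dw[1];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  bool hb = bias.isNotNull();
  NumericVector b = hb ? NumericVector(bias) : NumericVector(0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* kc = w.begin() + (size_t)KH * KW * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double bc = hb ? b[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bc;
          for (int kw = 0; kw < KW; ++kw) {
            int wi = wo * stride + kw - pl;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (size_t)H * wi;
            const double* krow = kc + (size_t)KH * kw;
            for (int kh = 0; kh < KH; ++kh) {
              int hi = ho * stride + kh - pt;
              if (hi < 0 || hi >= H) continue;
              acc += xcol[hi] * krow[kh];
            }
          }
          yc[(size_t)Ho * wo + ho] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                      int stride, int pt, int pl, bool need_gx, bool has_bias) {
  int dx[4]; get_dims4(x, dx);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  int KH = dw[0], KW = dw[1];
  IntegerVector dg = gy.attr("dim");
  int Ho = dg[0], Wo = dg[1];
  NumericVector gw((size_t)KH * KW * C);
  gw.attr("dim") = IntegerVector::create(KH, KW, C);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  NumericVector gb(has_bias ? C : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* kc = w.begin() + (size_t)KH * KW * c;
      const double* gyc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gwc = gw.begin() + (size_t)KH * KW * c;
      double* gxc = need_gx ? gx.begin() + (size_t)H * W * (c + (size_t)C * n) : NULL;
      double gbacc = 0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double gval = gyc[(size_t)Ho * wo + ho];
          if (gval == 0.0) continue;
          gbacc += gval;
          for (int kw = 0; kw < KW; ++kw) {
            int wi = wo * stride + kw - pl;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              int hi = ho * stride + kh - pt;
              if (hi < 0 || hi >= H) continue;
              gwc[(size_t)KH * kw + kh] += gval * xc[hi + (size_t)H * wi];
              if (need_gx) gxc[hi + (size_t)H * wi] += gval * kc[(size_t)KH * kw + kh];
            }
          }
        }
      if (has_bias) gb[c] += gbacc;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride) {
  int dx[4]; get_dims4(x, dx);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based flat index into x
  for (int n = 0; n < N; ++n) for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
    size_t base = (size_t)H * W * (c + (size_t)C * n);
    for (int wo = 0; wo < Wo; ++wo) for (int ho = 0; ho < Ho; ++ho) {
      double best = R_NegInf; int bi = 0;
      for (int kw = 0; kw < k; ++kw) for (int kh = 0; kh < k; ++kh) {
        int hi = ho * stride + kh, wi = wo * stride + kw;
        double v = xc[hi + (size_t)H * wi];
        if (v > best) { best = v; bi = hi + H * wi; }
      }
      size_t off = (size_t)Ho * Wo * (c + (size_t)C * n) + (size_t)Ho * wo + ho;
      y[off] = best;
      idx[off] = (int)(base + bi);
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  size_t total = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}
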