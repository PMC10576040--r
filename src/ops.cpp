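// Low-level kernels for the detector.
//
// Activations flow through the network as single-precision "ftensors": R
// raw vectors holding IEEE floats, with an integer `fdim` attribute
// (H, W, C, N), column-major, so a (channel, image) plane is a contiguous
// block of H*W floats. Parameters stay as R doubles and are converted per
// call (they are small). Convolutions are im2col + sgemm; depthwise and
// pointwise convolutions take direct paths. Batch-norm statistics are
// accumulated in double.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline float* FP(RawVector& x) {
  return reinterpret_cast<float*>(RAW(x));
}
static inline const float* FPc(const RawVector& x) {
  return reinterpret_cast<const float*>(RAW(x));
}

static IntegerVector fdim4(const RawVector& x) {
  RObject d = x.attr("fdim");
  if (d.isNULL()) stop("not an ftensor (missing fdim)");
  IntegerVector dd(d);
  if (dd.size() != 4) stop("ftensor must be 4-d (H, W, C, N)");
  return dd;
}

static RawVector make_ft(int H, int W, int C, int N) {
  RawVector r((R_xlen_t)4 * H * W * C * N);
  r.attr("fdim") = IntegerVector::create(H, W, C, N);
  return r;
}

static void to_float(const double* src, float* dst, R_xlen_t n) {
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

// ---- conversions -----------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_d2f(NumericVector x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) d = IntegerVector::create(d[0], d[1], d[2], 1);
  if (d.size() != 4) stop("expected a 3-d or 4-d array");
  RawVector r = make_ft(d[0], d[1], d[2], d[3]);
  to_float(REAL(x), FP(r), x.size());
  return r;
}

// [[Rcpp::export]]
NumericVector cpp_f2d(RawVector x) {
  IntegerVector d = fdim4(x);
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2] * d[3];
  NumericVector y(n);
  y.attr("dim") = d;
  const float* p = FPc(x);
  for (R_xlen_t i = 0; i < n; ++i) REAL(y)[i] = p[i];
  return y;
}

// [[Rcpp::export]]
IntegerVector cpp_fdim(RawVector x) { return fdim4(x); }

// ---- elementwise -----------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_silu_fwd(RawVector x) {
  IntegerVector d = fdim4(x);
  RawVector y = make_ft(d[0], d[1], d[2], d[3]);
  const float* p = FPc(x);
  float* q = FP(y);
  const R_xlen_t n = x.size() / 4;
  for (R_xlen_t i = 0; i < n; ++i)
    q[i] = p[i] / (1.0f + std::exp(-p[i]));
  return y;
}

// [[Rcpp::export]]
RawVector cpp_silu_bwd(RawVector x, RawVector gy) {
  IntegerVector d = fdim4(x);
  RawVector g = make_ft(d[0], d[1], d[2], d[3]);
  const float* p = FPc(x);
  const float* gp = FPc(gy);
  float* q = FP(g);
  const R_xlen_t n = x.size() / 4;
  for (R_xlen_t i = 0; i < n; ++i) {
    const float s = 1.0f / (1.0f + std::exp(-p[i]));
    q[i] = gp[i] * (s * (1.0f + p[i] * (1.0f - s)));
  }
  return g;
}

// [[Rcpp::export]]
RawVector cpp_sigmoid_fwd(RawVector x) {
  IntegerVector d = fdim4(x);
  RawVector y = make_ft(d[0], d[1], d[2], d[3]);
  const float* p = FPc(x);
  float* q = FP(y);
  const R_xlen_t n = x.size() / 4;
  for (R_xlen_t i = 0; i < n; ++i) q[i] = 1.0f / (1.0f + std::exp(-p[i]));
  return y;
}

// [[Rcpp::export]]
RawVector cpp_sigmoid_bwd(RawVector y, RawVector gy) {
  IntegerVector d = fdim4(y);
  RawVector g = make_ft(d[0], d[1], d[2], d[3]);
  const float* p = FPc(y);
  const float* gp = FPc(gy);
  float* q = FP(g);
  const R_xlen_t n = y.size() / 4;
  for (R_xlen_t i = 0; i < n; ++i) q[i] = gp[i] * p[i] * (1.0f - p[i]);
  return g;
}

// elementwise logistic on a plain numeric vector (decode/loss hot path)
// [[Rcpp::export]]
NumericVector cpp_sigmoid(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = REAL(x);
  double* q = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = 1.0 / (1.0 + std::exp(-p[i]));
  return y;
}

// [[Rcpp::export]]
RawVector cpp_add(RawVector a, RawVector b) {
  IntegerVector d = fdim4(a);
  RawVector y = make_ft(d[0], d[1], d[2], d[3]);
  const float* pa = FPc(a);
  const float* pb = FPc(b);
  float* q = FP(y);
  const R_xlen_t n = a.size() / 4;
  if (b.size() != a.size()) stop("add shape mismatch");
  for (R_xlen_t i = 0; i < n; ++i) q[i] = pa[i] + pb[i];
  return y;
}

// ---- gating helpers (SE / ECA) --------------------------------------------

// per-(channel, image) means -> numeric C*N
// [[Rcpp::export]]
NumericVector cpp_gap_fwd(RawVector x) {
  IntegerVector d = fdim4(x);
  const size_t P = (size_t)d[0] * d[1];
  const int CN = d[2] * d[3];
  NumericVector out(CN);
  const float* p = FPc(x);
  for (int c = 0; c < CN; ++c) {
    double s = 0.0;
    const float* q = p + P * c;
    for (size_t i = 0; i < P; ++i) s += q[i];
    out[c] = s / P;
  }
  return out;
}

// broadcast per-(channel, image) gains: y = x * g
// [[Rcpp::export]]
RawVector cpp_bcast_mul(RawVector x, NumericVector g) {
  IntegerVector d = fdim4(x);
  const size_t P = (size_t)d[0] * d[1];
  const int CN = d[2] * d[3];
  if (g.size() != CN) stop("gain length mismatch");
  RawVector y = make_ft(d[0], d[1], d[2], d[3]);
  const float* p = FPc(x);
  float* q = FP(y);
  for (int c = 0; c < CN; ++c) {
    const float gv = (float)g[c];
    const float* a = p + P * c;
    float* b = q + P * c;
    for (size_t i = 0; i < P; ++i) b[i] = a[i] * gv;
  }
  return y;
}

// broadcast add of per-(channel, image) values scaled by 1/(H*W)
// [[Rcpp::export]]
RawVector cpp_bcast_addscaled(RawVector x, NumericVector g) {
  IntegerVector d = fdim4(x);
  const size_t P = (size_t)d[0] * d[1];
  const int CN = d[2] * d[3];
  RawVector y = make_ft(d[0], d[1], d[2], d[3]);
  const float* p = FPc(x);
  float* q = FP(y);
  for (int c = 0; c < CN; ++c) {
    const float gv = (float)(g[c] / P);
    const float* a = p + P * c;
    float* b = q + P * c;
    for (size_t i = 0; i < P; ++i) b[i] = a[i] + gv;
  }
  return y;
}

// per-(channel, image) sum of x * y -> numeric C*N
// [[Rcpp::export]]
NumericVector cpp_plane_dot(RawVector x, RawVector y) {
  IntegerVector d = fdim4(x);
  const size_t P = (size_t)d[0] * d[1];
  const int CN = d[2] * d[3];
  NumericVector out(CN);
  const float* p = FPc(x);
  const float* q = FPc(y);
  for (int c = 0; c < CN; ++c) {
    double s = 0.0;
    const float* a = p + P * c;
    const float* b = q + P * c;
    for (size_t i = 0; i < P; ++i) s += (double)a[i] * b[i];
    out[c] = s;
  }
  return out;
}

// ---- convolution -----------------------------------------------------------

// Fill A (nrows x k*k*Cg) starting at row row0 with patches of channels
// [c0, c0+Cg) of one image.
static void im2col(const float* x, int H, int W, int c0, int Cg,
                   int k, int stride, int pad, int Ho, int Wo,
                   float* Amem, size_t nrows, size_t row0) {
  for (int ci = 0; ci < Cg; ++ci) {
    const float* plane = x + (size_t)(c0 + ci) * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        float* acol = Amem + (size_t)r * nrows + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          float* dst = acol + (size_t)Ho * wo;
          if (w < 0 || w >= W) {
            std::fill(dst, dst + Ho, 0.0f);
            continue;
          }
          const float* colp = plane + (size_t)w * H;
          int lo = 0;
          while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + kh >= H) --hi;
          for (int ho = 0; ho < lo; ++ho) dst[ho] = 0.0f;
          if (stride == 1) {
            const float* src = colp - pad + kh + lo;
            for (int ho = lo; ho < hi; ++ho) dst[ho] = src[ho - lo];
          } else {
            for (int ho = lo; ho < hi; ++ho)
              dst[ho] = colp[ho * stride - pad + kh];
          }
          for (int ho = hi; ho < Ho; ++ho) dst[ho] = 0.0f;
        }
      }
    }
  }
}

static void col2im_add(const float* Amem, size_t nrows, size_t row0,
                       float* gx, int H, int W, int c0, int Cg,
                       int k, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cg; ++ci) {
    float* plane = gx + (size_t)(c0 + ci) * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        const float* acol = Amem + (size_t)r * nrows + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          float* colp = plane + (size_t)w * H;
          const float* src = acol + (size_t)Ho * wo;
          int lo = 0;
          while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + kh >= H) --hi;
          if (stride == 1) {
            float* d = colp - pad + kh + lo;
            for (int ho = lo; ho < hi; ++ho) d[ho - lo] += src[ho];
          } else {
            for (int ho = lo; ho < hi; ++ho)
              colp[ho * stride - pad + kh] += src[ho];
          }
        }
      }
    }
  }
}

static void dw_fwd(const float* x, const float* wf, float* y, int H, int W,
                   int C, int Cout, int k, int stride, int pad,
                   int Ho, int Wo) {
  const int mult = Cout / C;
  for (int co = 0; co < Cout; ++co) {
    const int ci = co / mult;
    const float* plane = x + (size_t)ci * H * W;
    const float* wk = wf + (size_t)k * k * co;
    float* yp = y + (size_t)Ho * Wo * co;
    std::fill(yp, yp + (size_t)Ho * Wo, 0.0f);
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const float wv = wk[kh + k * kw];
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          const float* colp = plane + (size_t)w * H;
          float* dst = yp + (size_t)Ho * wo;
          int lo = 0;
          while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + kh >= H) --hi;
          if (stride == 1) {
            const float* src = colp - pad + kh + lo;
            for (int ho = lo; ho < hi; ++ho) dst[ho] += wv * src[ho - lo];
          } else {
            for (int ho = lo; ho < hi; ++ho)
              dst[ho] += wv * colp[ho * stride - pad + kh];
          }
        }
      }
  }
}

static void dw_bwd(const float* x, const float* wf, const float* gy,
                   float* gx, double* gw, int H, int W, int C, int Cout,
                   int k, int stride, int pad, int Ho, int Wo) {
  const int mult = Cout / C;
  for (int co = 0; co < Cout; ++co) {
    const int ci = co / mult;
    const float* plane = x + (size_t)ci * H * W;
    float* gplane = gx + (size_t)ci * H * W;
    const float* wk = wf + (size_t)k * k * co;
    const float* gyp = gy + (size_t)Ho * Wo * co;
    double* gwk = gw + (size_t)k * k * co;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const float wv = wk[kh + k * kw];
        double acc = 0.0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          const float* colp = plane + (size_t)w * H;
          float* gcolp = gplane + (size_t)w * H;
          const float* gsrc = gyp + (size_t)Ho * wo;
          int lo = 0;
          while (lo < Ho && lo * stride - pad + kh < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + kh >= H) --hi;
          if (stride == 1) {
            const float* xr = colp - pad + kh + lo;
            float* gr = gcolp - pad + kh + lo;
            for (int ho = lo; ho < hi; ++ho) {
              acc += (double)gsrc[ho] * xr[ho - lo];
              gr[ho - lo] += wv * gsrc[ho];
            }
          } else {
            for (int ho = lo; ho < hi; ++ho) {
              const int h = ho * stride - pad + kh;
              acc += (double)gsrc[ho] * colp[h];
              gcolp[h] += wv * gsrc[ho];
            }
          }
        }
        gwk[kh + k * kw] += acc;
      }
  }
}

// [[Rcpp::export]]
RawVector cpp_conv2d_fwd(RawVector x, NumericVector wgt,
                         Nullable<NumericVector> bias,
                         int stride, int pad, int groups) {
  IntegerVector xd = fdim4(x);
  IntegerVector wd = wgt.attr("dim");
  if (wd.size() != 4) stop("weight must be 4-d");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cg * groups) stop("in_channels/groups mismatch");
  if (Cout % groups != 0) stop("out_channels not divisible by groups");
  const int Coutg = Cout / groups;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int L = Ho * Wo;

  std::vector<float> wf((size_t)k * k * Cg * Cout);
  to_float(REAL(wgt), wf.data(), wf.size());
  std::vector<float> bf;
  if (bias.isNotNull()) {
    NumericVector b(bias);
    if ((int)b.size() != Cout) stop("bias length mismatch");
    bf.resize(Cout);
    to_float(REAL(b), bf.data(), Cout);
  }

  RawVector y = make_ft(Ho, Wo, Cout, N);
  float* yp = FP(y);
  const float* xf = FPc(x);

  const bool pointwise = (k == 1 && stride == 1 && groups == 1);
  const bool depthwise = (groups == C && Cg == 1);

  if (depthwise) {
    for (int n = 0; n < N; ++n)
      dw_fwd(xf + (size_t)n * H * W * C, wf.data(),
             yp + (size_t)L * Cout * n, H, W, C, Cout, k, stride, pad,
             Ho, Wo);
  } else if (pointwise) {
    arma::fmat Wm(wf.data(), C, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      const arma::fmat Am(const_cast<float*>(xf + (size_t)n * H * W * C),
                          L, C, false, true);
      arma::fmat Ym(yp + (size_t)L * Cout * n, L, Cout, false, true);
      Ym = Am * Wm;
    }
  } else {
    const size_t R = (size_t)k * k * Cg;
    const size_t NL = (size_t)N * L;
    arma::fmat A(NL, R);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n)
        im2col(xf + (size_t)n * H * W * C, H, W, g * Cg, Cg, k, stride,
               pad, Ho, Wo, A.memptr(), NL, (size_t)n * L);
      arma::fmat Wm(wf.data() + R * (g * Coutg), R, Coutg, false, true);
      arma::fmat Yg = A * Wm; // NL x Coutg
      for (int co = 0; co < Coutg; ++co) {
        const float* src = Yg.colptr(co);
        for (int n = 0; n < N; ++n)
          std::copy(src + (size_t)n * L, src + (size_t)(n + 1) * L,
                    yp + (size_t)L * (g * Coutg + co) +
                      (size_t)L * Cout * n);
      }
    }
  }
  if (!bf.empty())
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        float* d = yp + (size_t)L * co + (size_t)L * Cout * n;
        const float b = bf[co];
        for (int l = 0; l < L; ++l) d[l] += b;
      }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(RawVector x, NumericVector wgt, RawVector gy,
                    int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = fdim4(x), yd = fdim4(gy);
  IntegerVector wd = wgt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cg = wd[2], Cout = wd[3];
  const int Coutg = Cout / groups;
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Cout || yd[3] != N) stop("grad shape mismatch");
  const int L = Ho * Wo;

  std::vector<float> wf((size_t)k * k * Cg * Cout);
  to_float(REAL(wgt), wf.data(), wf.size());
  const float* xf = FPc(x);
  const float* gyf = FPc(gy);

  RawVector gx = make_ft(H, W, C, N);
  float* gxf = FP(gx);
  std::fill(gxf, gxf + (size_t)H * W * C * N, 0.0f);
  std::vector<double> gwacc((size_t)k * k * Cg * Cout, 0.0);
  std::vector<double> gb(has_bias ? Cout : 0, 0.0);

  const bool pointwise = (k == 1 && stride == 1 && groups == 1);
  const bool depthwise = (groups == C && Cg == 1);

  if (depthwise) {
    for (int n = 0; n < N; ++n)
      dw_bwd(xf + (size_t)n * H * W * C, wf.data(),
             gyf + (size_t)L * Cout * n, gxf + (size_t)n * H * W * C,
             gwacc.data(), H, W, C, Cout, k, stride, pad, Ho, Wo);
  } else if (pointwise) {
    arma::fmat gW(C, Cout, arma::fill::zeros);
    arma::fmat Wm(wf.data(), C, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      const arma::fmat Am(const_cast<float*>(xf + (size_t)n * H * W * C),
                          L, C, false, true);
      const arma::fmat Gy(const_cast<float*>(gyf + (size_t)L * Cout * n),
                          L, Cout, false, true);
      gW += Am.t() * Gy;
      arma::fmat Gx(gxf + (size_t)n * H * W * C, L, C, false, true);
      Gx = Gy * Wm.t();
    }
    for (size_t i = 0; i < gwacc.size(); ++i) gwacc[i] = gW.memptr()[i];
  } else {
    const size_t R = (size_t)k * k * Cg;
    const size_t NL = (size_t)N * L;
    arma::fmat A(NL, R);
    arma::fmat Gyb(NL, Coutg);
    arma::fmat gW(R, Cout, arma::fill::zeros);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n)
        im2col(xf + (size_t)n * H * W * C, H, W, g * Cg, Cg, k, stride,
               pad, Ho, Wo, A.memptr(), NL, (size_t)n * L);
      for (int co = 0; co < Coutg; ++co) {
        float* dst = Gyb.colptr(co);
        for (int n = 0; n < N; ++n) {
          const float* src = gyf + (size_t)L * (g * Coutg + co) +
            (size_t)L * Cout * n;
          std::copy(src, src + L, dst + (size_t)n * L);
        }
      }
      arma::fmat Wm(wf.data() + R * (g * Coutg), R, Coutg, false, true);
      gW.cols(g * Coutg, (g + 1) * Coutg - 1) = A.t() * Gyb;
      arma::fmat Gcols = Gyb * Wm.t(); // NL x R
      for (int n = 0; n < N; ++n)
        col2im_add(Gcols.memptr(), NL, (size_t)n * L,
                   gxf + (size_t)n * H * W * C, H, W, g * Cg, Cg, k,
                   stride, pad, Ho, Wo);
    }
    for (size_t i = 0; i < gwacc.size(); ++i) gwacc[i] = gW.memptr()[i];
  }
  if (has_bias)
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        const float* p = gyf + (size_t)L * co + (size_t)L * Cout * n;
        double s = 0.0;
        for (int l = 0; l < L; ++l) s += p[l];
        gb[co] += s;
      }

  NumericVector gw((R_xlen_t)gwacc.size());
  gw.attr("dim") = wd;
  for (size_t i = 0; i < gwacc.size(); ++i) REAL(gw)[i] = gwacc[i];
  List out = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) out["gb"] = NumericVector(gb.begin(), gb.end());
  return out;
}

// ---- batch norm ------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bn_fwd(RawVector x, NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var,
                double eps, double momentum, bool training) {
  IntegerVector xd = fdim4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t P = (size_t)H * W;
  const float* xp = FPc(x);
  RawVector y = make_ft(H, W, C, N);
  float* yp = FP(y);
  NumericVector mu(C), inv(C), rm = clone(run_mean), rv = clone(run_var);
  const double cnt = (double)P * N;

  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, ss = 0.0;
      for (int n = 0; n < N; ++n) {
        const float* p = xp + P * c + P * C * n;
        for (size_t i = 0; i < P; ++i) {
          s += p[i];
          ss += (double)p[i] * p[i];
        }
      }
      m = s / cnt;
      v = ss / cnt - m * m;
      if (v < 0) v = 0;
      rm[c] = (1.0 - momentum) * rm[c] + momentum * m;
      const double ub = cnt > 1 ? v * cnt / (cnt - 1.0) : v;
      rv[c] = (1.0 - momentum) * rv[c] + momentum * ub;
    } else {
      m = run_mean[c];
      v = run_var[c];
    }
    const double istd = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    inv[c] = istd;
    const float a = (float)(gamma[c] * istd);
    const float b = (float)(beta[c] - gamma[c] * istd * m);
    for (int n = 0; n < N; ++n) {
      const float* p = xp + P * c + P * C * n;
      float* q = yp + P * c + P * C * n;
      for (size_t i = 0; i < P; ++i) q[i] = a * p[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = inv,
                      _["run_mean"] = rm, _["run_var"] = rv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(RawVector x, RawVector gy, NumericVector gamma,
                NumericVector mean, NumericVector invstd) {
  IntegerVector xd = fdim4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t P = (size_t)H * W;
  const double cnt = (double)P * N;
  const float* xp = FPc(x);
  const float* gp = FPc(gy);
  RawVector gx = make_ft(H, W, C, N);
  float* op = FP(gx);
  NumericVector gg(C), gb(C);

  for (int c = 0; c < C; ++c) {
    const double m = mean[c], istd = invstd[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const float* xq = xp + P * c + P * C * n;
      const float* gq = gp + P * c + P * C * n;
      for (size_t i = 0; i < P; ++i) {
        sg += gq[i];
        sgx += (double)gq[i] * (xq[i] - m) * istd;
      }
    }
    gg[c] = sgx;
    gb[c] = sg;
    const double a = gamma[c] * istd / cnt;
    const float fm = (float)m, fistd = (float)istd, fa = (float)a;
    const float fsg = (float)sg, fsgx = (float)sgx, fcnt = (float)cnt;
    for (int n = 0; n < N; ++n) {
      const float* xq = xp + P * c + P * C * n;
      const float* gq = gp + P * c + P * C * n;
      float* oq = op + P * c + P * C * n;
      for (size_t i = 0; i < P; ++i) {
        const float xh = (xq[i] - fm) * fistd;
        oq[i] = fa * (fcnt * gq[i] - fsg - xh * fsgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// ---- pooling / upsampling --------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fwd(RawVector x, int k, int stride, int pad) {
  IntegerVector xd = fdim4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const float* xp = FPc(x);
  RawVector y = make_ft(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  float* yp = FP(y);
  int* ap = INTEGER(arg);
  const float ninf = -std::numeric_limits<float>::infinity();

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      const R_xlen_t base = (R_xlen_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          float best = ninf;
          int bidx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const float v = plane[h + (size_t)H * w];
              if (v > best) { best = v; bidx = h + H * w; }
            }
          }
          const R_xlen_t idx = base + ho + (R_xlen_t)Ho * wo;
          yp[idx] = best;
          ap[idx] = bidx;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
RawVector cpp_maxpool_bwd(RawVector gy, IntegerVector argmax,
                          IntegerVector xdim) {
  IntegerVector yd = fdim4(gy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = xdim[0], W = xdim[1];
  RawVector gx = make_ft(H, W, C, N);
  float* op = FP(gx);
  std::fill(op, op + (size_t)H * W * C * N, 0.0f);
  const float* gp = FPc(gy);
  const int* ap = INTEGER(argmax);
  const R_xlen_t Ly = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      float* plane = op + (size_t)H * W * (c + (size_t)C * n);
      const R_xlen_t base = Ly * (c + (size_t)C * n);
      for (R_xlen_t l = 0; l < Ly; ++l) {
        const int b = ap[base + l];
        if (b >= 0) plane[b] += gp[base + l];
      }
    }
  return gx;
}

// [[Rcpp::export]]
RawVector cpp_upsample2_fwd(RawVector x) {
  IntegerVector xd = fdim4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  RawVector y = make_ft(2 * H, 2 * W, C, N);
  const float* xp = FPc(x);
  float* yp = FP(y);
  const size_t CP = (size_t)C * N;
  for (size_t cn = 0; cn < CP; ++cn) {
    const float* pi = xp + (size_t)H * W * cn;
    float* po = yp + (size_t)4 * H * W * cn;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const float v = pi[h + (size_t)H * w];
        const size_t b = (size_t)2 * h + (size_t)2 * H * 2 * w;
        po[b] = v;
        po[b + 1] = v;
        po[b + 2 * H] = v;
        po[b + 2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
RawVector cpp_upsample2_bwd(RawVector gy) {
  IntegerVector yd = fdim4(gy);
  const int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  const int H = H2 / 2, W = W2 / 2;
  RawVector gx = make_ft(H, W, C, N);
  const float* gp = FPc(gy);
  float* op = FP(gx);
  const size_t CP = (size_t)C * N;
  for (size_t cn = 0; cn < CP; ++cn) {
    const float* pi = gp + (size_t)H2 * W2 * cn;
    float* po = op + (size_t)H * W * cn;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t b = (size_t)2 * h + (size_t)H2 * 2 * w;
        po[h + (size_t)H * w] =
          pi[b] + pi[b + 1] + pi[b + H2] + pi[b + H2 + 1];
      }
  }
  return gx;
}

// ---- concatenation ---------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_concat_channels(List xs) {
  const int K = xs.size();
  std::vector<RawVector> vs;
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> Cs(K);
  for (int i = 0; i < K; ++i) {
    RawVector v = xs[i];
    IntegerVector d = fdim4(v);
    if (i == 0) { H = d[0]; W = d[1]; N = d[3]; }
    else if (d[0] != H || d[1] != W || d[3] != N)
      stop("concat shape mismatch");
    Cs[i] = d[2];
    Ctot += d[2];
    vs.push_back(v);
  }
  RawVector y = make_ft(H, W, Ctot, N);
  float* yp = FP(y);
  const size_t P = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    size_t at = 0;
    for (int i = 0; i < K; ++i) {
      const float* src = FPc(vs[i]) + P * Cs[i] * n;
      std::copy(src, src + P * Cs[i], yp + P * Ctot * n + P * at);
      at += Cs[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
RawVector cpp_slice_channels(RawVector x, int c0, int c1) {
  IntegerVector d = fdim4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cs = c1 - c0 + 1;
  RawVector y = make_ft(H, W, Cs, N);
  const size_t P = (size_t)H * W;
  const float* xp = FPc(x);
  float* yp = FP(y);
  for (int n = 0; n < N; ++n)
    std::copy(xp + P * ((size_t)C * n + c0 - 1),
              xp + P * ((size_t)C * n + c0 - 1) + P * Cs,
              yp + P * (size_t)Cs * n);
  return y;
}

// ---- data pipeline (double precision, R arrays) ----------------------------

// Bilinear resize with half-pixel centers.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("expected a 4-d array");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    fh[i] = s - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    fw[j] = s - w0[j];
  }
  const size_t CP = (size_t)C * N;
  for (size_t cn = 0; cn < CP; ++cn) {
    const double* pi = xp + (size_t)H * W * cn;
    double* po = yp + (size_t)Ho * Wo * cn;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double a = pi[h0[i] + (size_t)H * w0[j]];
        const double b = pi[h1[i] + (size_t)H * w0[j]];
        const double c = pi[h0[i] + (size_t)H * w1[j]];
        const double d = pi[h1[i] + (size_t)H * w1[j]];
        const double top = a + (c - a) * fw[j];
        const double bot = b + (d - b) * fw[j];
        po[i + (size_t)Ho * j] = top + (bot - top) * fh[i];
      }
  }
  return y;
}

// Nearest-neighbor inverse-affine warp of an (hq, wq, 3) patch about its
// center: rotation th, scale sc, translation (tx, ty); out-of-range
// pixels take `fill`.
// [[Rcpp::export]]
NumericVector cpp_warp_affine_nn(NumericVector img, double th, double sc,
                                 double tx, double ty, double fill) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3 || d[2] != 3) stop("expected an (H, W, 3) image");
  const int H = d[0], W = d[1];
  NumericVector out((R_xlen_t)H * W * 3);
  out.attr("dim") = d;
  const double* ip = REAL(img);
  double* op = REAL(out);
  const double cx = (W + 1) / 2.0, cy = (H + 1) / 2.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < W; ++j) {
    const double dx = (j + 1) - cx - tx;
    for (int i = 0; i < H; ++i) {
      const double dy = (i + 1) - cy - ty;
      const double sx = (ct * dx + st * dy) / sc + cx;
      const double sy = (-st * dx + ct * dy) / sc + cy;
      const int sj = (int)std::lround(sx) - 1;
      const int si = (int)std::lround(sy) - 1;
      const R_xlen_t o = i + (R_xlen_t)H * j;
      if (si >= 0 && si < H && sj >= 0 && sj < W) {
        const R_xlen_t s = si + (R_xlen_t)H * sj;
        op[o] = ip[s];
        op[o + (R_xlen_t)H * W] = ip[s + (R_xlen_t)H * W];
        op[o + (R_xlen_t)2 * H * W] = ip[s + (R_xlen_t)2 * H * W];
      } else {
        op[o] = fill;
        op[o + (R_xlen_t)H * W] = fill;
        op[o + (R_xlen_t)2 * H * W] = fill;
      }
    }
  }
  return out;
}

// HSV-space photometric jitter: hue gain (wrapped), saturation and value
// gains (clipped), then a contrast gain about 0.5; all in [0, 1].
// [[Rcpp::export]]
NumericVector cpp_hsv_jitter(NumericVector img, double rh, double rs,
                             double rv, double rc) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3 || d[2] != 3) stop("expected an (H, W, 3) image");
  const R_xlen_t P = (R_xlen_t)d[0] * d[1];
  NumericVector out((R_xlen_t)P * 3);
  out.attr("dim") = d;
  const double* r = REAL(img);
  const double* g = r + P;
  const double* b = g + P;
  double* ro = REAL(out);
  double* go = ro + P;
  double* bo = go + P;
  for (R_xlen_t i = 0; i < P; ++i) {
    const double R0 = r[i], G0 = g[i], B0 = b[i];
    const double mx = std::max(R0, std::max(G0, B0));
    const double mn = std::min(R0, std::min(G0, B0));
    const double dlt = mx - mn;
    double h = 0.0;
    if (dlt > 0) {
      if (mx == R0) {
        h = (G0 - B0) / dlt;
        h -= 6.0 * std::floor(h / 6.0);
      } else if (mx == G0) h = (B0 - R0) / dlt + 2.0;
      else h = (R0 - G0) / dlt + 4.0;
      h /= 6.0;
    }
    double s = mx > 0 ? dlt / mx : 0.0;
    double v = mx;
    h = h * rh;
    h -= std::floor(h);
    s = std::min(s * rs, 1.0);
    v = std::min(v * rv, 1.0);
    const double hh = h * 6.0;
    const int k = (int)std::floor(hh) % 6;
    const double f = hh - std::floor(hh);
    const double p = v * (1 - s), q = v * (1 - s * f),
                 t = v * (1 - s * (1 - f));
    double R1, G1, B1;
    switch (k) {
      case 0: R1 = v; G1 = t; B1 = p; break;
      case 1: R1 = q; G1 = v; B1 = p; break;
      case 2: R1 = p; G1 = v; B1 = t; break;
      case 3: R1 = p; G1 = q; B1 = v; break;
      case 4: R1 = t; G1 = p; B1 = v; break;
      default: R1 = v; G1 = p; B1 = q; break;
    }
    R1 = (R1 - 0.5) * rc + 0.5;
    G1 = (G1 - 0.5) * rc + 0.5;
    B1 = (B1 - 0.5) * rc + 0.5;
    ro[i] = std::min(std::max(R1, 0.0), 1.0);
    go[i] = std::min(std::max(G1, 0.0), 1.0);
    bo[i] = std::min(std::max(B1, 0.0), 1.0);
  }
  return out;
}
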