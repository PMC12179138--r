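// Dense CPU kernels for the tensor engine: grouped/dilated 2-D convolution via
// im2col + BLAS GEMM, batch normalization, and max/average pooling.
//
// Array layout everywhere: column-major (H, W, C, N) — height is the fastest
// axis, matching R's array order. Weights are (kh, kw, Cin/groups, Cout).
// Kernels are templated on the accumulation type so convolutions can run in
// single precision (the reduced-precision training mode) or double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

template <typename T>
static void im2col_t(const double* x, int H, int W, int Cg,
                     int kh, int kw, int stride, int ph, int pw, int dil,
                     int Ho, int Wo, T* col) {
  // col: (kh*kw*Cg) x (Ho*Wo); row p = ikh + kh*(ikw + kw*c) matches the
  // column-major weight layout (kh, kw, Cg, Cout).
  const int K = kh * kw * Cg;
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pw;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - ph;
      T* colp = col + (size_t)K * (ho + (size_t)Ho * wo);
      for (int c = 0; c < Cg; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int ikw = 0; ikw < kw; ++ikw) {
          const int wi = w0 + ikw * dil;
          const bool wok = (wi >= 0 && wi < W);
          T* dst = colp + kh * (ikw + kw * c);
          if (!wok) {
            for (int ikh = 0; ikh < kh; ++ikh) dst[ikh] = (T)0;
          } else {
            const double* xw = xc + (size_t)H * wi;
            for (int ikh = 0; ikh < kh; ++ikh) {
              const int hi = h0 + ikh * dil;
              dst[ikh] = (hi >= 0 && hi < H) ? (T)xw[hi] : (T)0;
            }
          }
        }
      }
    }
  }
}

template <typename T>
static void col2im_t(const T* col, int H, int W, int Cg,
                     int kh, int kw, int stride, int ph, int pw, int dil,
                     int Ho, int Wo, double* dx) {
  const int K = kh * kw * Cg;
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pw;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - ph;
      const T* colp = col + (size_t)K * (ho + (size_t)Ho * wo);
      for (int c = 0; c < Cg; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int ikw = 0; ikw < kw; ++ikw) {
          const int wi = w0 + ikw * dil;
          if (wi < 0 || wi >= W) continue;
          double* xw = xc + (size_t)H * wi;
          const T* src = colp + kh * (ikw + kw * c);
          for (int ikh = 0; ikh < kh; ++ikh) {
            const int hi = h0 + ikh * dil;
            if (hi >= 0 && hi < H) xw[hi] += (double)src[ikh];
          }
        }
      }
    }
  }
}

template <typename T>
static NumericVector conv_fwd_t(const NumericVector& x, const IntegerVector& xd,
                                const NumericVector& w, const IntegerVector& wd,
                                const NumericVector& b,
                                int stride, int ph, int pw, int dil, int groups) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int Coutg = Cout / groups;
  const int Ho = out_size(H, kh, stride, ph, dil);
  const int Wo = out_size(W, kw, stride, pw, dil);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty (input %dx%d)", H, W);
  if (C != Cg * groups) stop("channel/group mismatch: C=%d, Cg=%d, groups=%d", C, Cg, groups);
  const int K = kh * kw * Cg;
  const size_t P = (size_t)Ho * Wo;
  const bool has_bias = b.size() > 0;

  arma::Mat<T> Wm(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) Wm.memptr()[i] = (T)w[i];
  arma::Mat<T> col(K, P * (size_t)N);  // all samples of one group batched
  NumericVector y(P * Cout * (size_t)N);
  double* yr = REAL(y);
  const double* xr = REAL(x);

  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      const double* xs = xr + (size_t)H * W * ((size_t)g * Cg + (size_t)C * n);
      im2col_t<T>(xs, H, W, Cg, kh, kw, stride, ph, pw, dil, Ho, Wo,
                  col.colptr(P * (size_t)n));
    }
    const arma::Mat<T> Wg(const_cast<T*>(Wm.colptr((size_t)g * Coutg)), K, Coutg, false, true);
    arma::Mat<T> yg = col.t() * Wg;  // (P*N) x Coutg
    for (int n = 0; n < N; ++n) {
      double* yp = yr + P * ((size_t)g * Coutg + (size_t)Cout * n);
      for (int co = 0; co < Coutg; ++co) {
        const double bb = has_bias ? b[g * Coutg + co] : 0.0;
        double* ypc = yp + (size_t)co * P;
        const T* ygc = yg.colptr(co) + P * (size_t)n;
        for (size_t i = 0; i < P; ++i) ypc[i] = (double)ygc[i] + bb;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector b, int stride, int ph, int pw,
                             int dil, int groups, bool single) {
  if (single) return conv_fwd_t<float>(x, xd, w, wd, b, stride, ph, pw, dil, groups);
  return conv_fwd_t<double>(x, xd, w, wd, b, stride, ph, pw, dil, groups);
}

template <typename T>
static List conv_bwd_t(const NumericVector& x, const IntegerVector& xd,
                       const NumericVector& w, const IntegerVector& wd,
                       const NumericVector& dy,
                       int stride, int ph, int pw, int dil, int groups,
                       bool need_dx, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int Coutg = Cout / groups;
  const int Ho = out_size(H, kh, stride, ph, dil);
  const int Wo = out_size(W, kw, stride, pw, dil);
  const int K = kh * kw * Cg;
  const size_t P = (size_t)Ho * Wo;

  arma::Mat<T> Wm(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) Wm.memptr()[i] = (T)w[i];
  arma::Mat<T> dWm(K, Cout, arma::fill::zeros);
  arma::Mat<T> col(K, P * (size_t)N), dyg(P * (size_t)N, Coutg);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  NumericVector db(has_bias ? Cout : 0);
  const double* xr = REAL(x);
  const double* dyr = REAL(dy);

  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      const double* xs = xr + (size_t)H * W * ((size_t)g * Cg + (size_t)C * n);
      im2col_t<T>(xs, H, W, Cg, kh, kw, stride, ph, pw, dil, Ho, Wo,
                  col.colptr(P * (size_t)n));
      const double* dyp = dyr + P * ((size_t)g * Coutg + (size_t)Cout * n);
      for (int co = 0; co < Coutg; ++co) {
        T* dst = dyg.colptr(co) + P * (size_t)n;
        const double* src = dyp + (size_t)co * P;
        for (size_t i = 0; i < P; ++i) dst[i] = (T)src[i];
      }
      if (has_bias) {
        for (int co = 0; co < Coutg; ++co) {
          double s = 0.0;
          const double* dyc = dyp + (size_t)co * P;
          for (size_t i = 0; i < P; ++i) s += dyc[i];
          db[g * Coutg + co] += s;
        }
      }
    }
    dWm.cols((size_t)g * Coutg, (size_t)(g + 1) * Coutg - 1) = col * dyg;
    if (need_dx) {
      const arma::Mat<T> Wg(const_cast<T*>(Wm.colptr((size_t)g * Coutg)), K, Coutg, false, true);
      arma::Mat<T> dcol = Wg * dyg.t();  // K x (P*N)
      for (int n = 0; n < N; ++n) {
        double* dxs = REAL(dx) + (size_t)H * W * ((size_t)g * Cg + (size_t)C * n);
        col2im_t<T>(dcol.colptr(P * (size_t)n), H, W, Cg, kh, kw, stride,
                    ph, pw, dil, Ho, Wo, dxs);
      }
    }
  }
  NumericVector dw((size_t)K * Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) dw[i] = (double)dWm.memptr()[i];
  dw.attr("dim") = wd;
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector dy, int stride, int ph, int pw,
                    int dil, int groups, bool need_dx, bool has_bias, bool single) {
  if (single) return conv_bwd_t<float>(x, xd, w, wd, dy, stride, ph, pw, dil, groups, need_dx, has_bias);
  return conv_bwd_t<double>(x, xd, w, wd, dy, stride, ph, pw, dil, groups, need_dx, has_bias);
}

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t S = (size_t)H * W;
  NumericVector mean(C), var(C);
  const double* xr = REAL(x);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xs = xr + S * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < S; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    const double m = s / ((double)S * N);
    double v = s2 / ((double)S * N) - m * m;
    mean[c] = m;
    var[c] = v > 0.0 ? v : 0.0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_fwd(NumericVector x, IntegerVector xd,
                         NumericVector gamma, NumericVector beta,
                         NumericVector mean, NumericVector invstd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t S = (size_t)H * W;
  NumericVector y(x.size());
  const double* xr = REAL(x);
  double* yr = REAL(y);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - a * mean[c];
      const double* xs = xr + S * ((size_t)c + (size_t)C * n);
      double* ys = yr + S * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < S; ++i) ys[i] = a * xs[i] + b;
    }
  }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, IntegerVector xd, NumericVector dy,
                NumericVector gamma, NumericVector mean, NumericVector invstd,
                bool training) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t S = (size_t)H * W;
  const double m = (double)S * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xr = REAL(x);
  const double* dyr = REAL(dy);
  double* dxr = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = S * ((size_t)c + (size_t)C * n);
      const double* xs = xr + off;
      const double* ds = dyr + off;
      for (size_t i = 0; i < S; ++i) {
        const double xh = (xs[i] - mean[c]) * invstd[c];
        sdy += ds[i];
        sdyx += ds[i] * xh;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = S * ((size_t)c + (size_t)C * n);
      const double* xs = xr + off;
      const double* ds = dyr + off;
      double* dd = dxr + off;
      if (training) {
        for (size_t i = 0; i < S; ++i) {
          const double xh = (xs[i] - mean[c]) * invstd[c];
          dd[i] = a * (ds[i] - sdy / m - xh * sdyx / m);
        }
      } else {
        for (size_t i = 0; i < S; ++i) dd[i] = a * ds[i];
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xd, int k, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  const size_t S = (size_t)H * W, P = (size_t)Ho * Wo;
  NumericVector y(P * C * (size_t)N);
  IntegerVector idx(P * C * (size_t)N);
  const double* xr = REAL(x);
  double* yr = REAL(y);
  int* ir = INTEGER(idx);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xr + S * ((size_t)c + (size_t)C * n);
      double* ys = yr + P * ((size_t)c + (size_t)C * n);
      int* is = ir + P * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int besti = -1;
          for (int ikw = 0; ikw < k; ++ikw) {
            const int wi = wo * stride - pad + ikw;
            if (wi < 0 || wi >= W) continue;
            for (int ikh = 0; ikh < k; ++ikh) {
              const int hi = ho * stride - pad + ikh;
              if (hi < 0 || hi >= H) continue;
              const double v = xs[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          ys[ho + (size_t)Ho * wo] = best;
          is[ho + (size_t)Ho * wo] = besti;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t S = (size_t)H * W;
  const size_t P = (size_t)dy.size() / ((size_t)C * N);
  NumericVector dx(S * C * (size_t)N);
  const double* dyr = REAL(dy);
  const int* ir = INTEGER(idx);
  double* dxr = REAL(dx);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = P * ((size_t)c + (size_t)C * n);
      double* dxs = dxr + S * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < P; ++i) {
        const int j = ir[off + i];
        if (j >= 0) dxs[j] += dyr[off + i];
      }
    }
  }
  dx.attr("dim") = xd;
  return dx;
}

// Average pooling; the divisor counts only in-bounds taps (padding excluded).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector xd, int k, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  const size_t S = (size_t)H * W, P = (size_t)Ho * Wo;
  NumericVector y(P * C * (size_t)N);
  const double* xr = REAL(x);
  double* yr = REAL(y);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xr + S * ((size_t)c + (size_t)C * n);
      double* ys = yr + P * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          int cnt = 0;
          for (int ikw = 0; ikw < k; ++ikw) {
            const int wi = wo * stride - pad + ikw;
            if (wi < 0 || wi >= W) continue;
            for (int ikh = 0; ikh < k; ++ikh) {
              const int hi = ho * stride - pad + ikh;
              if (hi < 0 || hi >= H) continue;
              s += xs[hi + (size_t)H * wi];
              ++cnt;
            }
          }
          ys[ho + (size_t)Ho * wo] = cnt > 0 ? s / cnt : 0.0;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, IntegerVector xd, int k, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  const size_t S = (size_t)H * W, P = (size_t)Ho * Wo;
  NumericVector dx(S * C * (size_t)N);
  const double* dyr = REAL(dy);
  double* dxr = REAL(dx);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* ds = dyr + P * ((size_t)c + (size_t)C * n);
      double* dxs = dxr + S * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int cnt = 0;
          for (int ikw = 0; ikw < k; ++ikw) {
            const int wi = wo * stride - pad + ikw;
            if (wi < 0 || wi >= W) continue;
            for (int ikh = 0; ikh < k; ++ikh) {
              const int hi = ho * stride - pad + ikh;
              if (hi >= 0 && hi < H) ++cnt;
            }
          }
          if (cnt == 0) continue;
          const double g = ds[ho + (size_t)Ho * wo] / cnt;
          for (int ikw = 0; ikw < k; ++ikw) {
            const int wi = wo * stride - pad + ikw;
            if (wi < 0 || wi >= W) continue;
            for (int ikh = 0; ikh < k; ++ikh) {
              const int hi = ho * stride - pad + ikh;
              if (hi >= 0 && hi < H) dxs[hi + (size_t)H * wi] += g;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  return dx;
}

// Depthwise convolution (groups == C, one filter per channel), direct loops
// with unit-stride inner loops over the height axis. Weight layout
// (kh, kw, 1, C). Used for the 5x5 and strip kernels of the attention core.

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector b, int stride, int ph, int pw,
                             int dil) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_size(H, kh, stride, ph, dil);
  const int Wo = out_size(W, kw, stride, pw, dil);
  const size_t S = (size_t)H * W, P = (size_t)Ho * Wo;
  const bool has_bias = b.size() > 0;
  NumericVector y(P * C * (size_t)N);
  const double* xr = REAL(x);
  const double* wr = REAL(w);
  double* yr = REAL(y);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xr + S * ((size_t)c + (size_t)C * n);
      double* ys = yr + P * ((size_t)c + (size_t)C * n);
      const double bb = has_bias ? b[c] : 0.0;
      for (size_t i = 0; i < P; ++i) ys[i] = bb;
      const double* wc = wr + (size_t)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo) {
        double* yo = ys + (size_t)Ho * wo;
        for (int ikw = 0; ikw < kw; ++ikw) {
          const int wi = wo * stride - pw + ikw * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xw = xs + (size_t)H * wi;
          for (int ikh = 0; ikh < kh; ++ikh) {
            const double wv = wc[ikh + kh * ikw];
            if (wv == 0.0) continue;
            const int hi0 = -ph + ikh * dil;
            if (stride == 1) {
              const int lo = hi0 < 0 ? -hi0 : 0;
              const int himax = H - hi0;
              const int up = Ho < himax ? Ho : himax;
              const double* xcol = xw + hi0;
              for (int ho = lo; ho < up; ++ho) yo[ho] += wv * xcol[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + hi0;
                if (hi >= 0 && hi < H) yo[ho] += wv * xw[hi];
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector dy, int stride, int ph, int pw, int dil,
                    bool need_dx, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_size(H, kh, stride, ph, dil);
  const int Wo = out_size(W, kw, stride, pw, dil);
  const size_t S = (size_t)H * W, P = (size_t)Ho * Wo;
  NumericVector dx(need_dx ? S * C * (size_t)N : 0);
  NumericVector dw((size_t)kh * kw * C);
  NumericVector db(has_bias ? C : 0);
  const double* xr = REAL(x);
  const double* wr = REAL(w);
  const double* dyr = REAL(dy);
  double* dxr = need_dx ? REAL(dx) : nullptr;
  double* dwr = REAL(dw);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xr + S * ((size_t)c + (size_t)C * n);
      const double* ds = dyr + P * ((size_t)c + (size_t)C * n);
      double* dxs = need_dx ? dxr + S * ((size_t)c + (size_t)C * n) : nullptr;
      const double* wc = wr + (size_t)kh * kw * c;
      double* dwc = dwr + (size_t)kh * kw * c;
      if (has_bias) {
        double s = 0.0;
        for (size_t i = 0; i < P; ++i) s += ds[i];
        db[c] += s;
      }
      for (int wo = 0; wo < Wo; ++wo) {
        const double* dyo = ds + (size_t)Ho * wo;
        for (int ikw = 0; ikw < kw; ++ikw) {
          const int wi = wo * stride - pw + ikw * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xw = xs + (size_t)H * wi;
          double* dxw = need_dx ? dxs + (size_t)H * wi : nullptr;
          for (int ikh = 0; ikh < kh; ++ikh) {
            const int hi0 = -ph + ikh * dil;
            const double wv = wc[ikh + kh * ikw];
            double acc = 0.0;
            if (stride == 1) {
              const int lo = hi0 < 0 ? -hi0 : 0;
              const int himax = H - hi0;
              const int up = Ho < himax ? Ho : himax;
              const double* xcol = xw + hi0;
              if (need_dx) {
                double* dxcol = dxw + hi0;
                for (int ho = lo; ho < up; ++ho) {
                  acc += dyo[ho] * xcol[ho];
                  dxcol[ho] += wv * dyo[ho];
                }
              } else {
                for (int ho = lo; ho < up; ++ho) acc += dyo[ho] * xcol[ho];
              }
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + hi0;
                if (hi < 0 || hi >= H) continue;
                acc += dyo[ho] * xw[hi];
                if (need_dx) dxw[hi] += wv * dyo[ho];
              }
            }
            dwc[ikh + kh * ikw] += acc;
          }
        }
      }
    }
  }
  dw.attr("dim") = wd;
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  const double* xr = REAL(x);
  double* yr = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i) yr[i] = xr[i] > 0.0 ? xr[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector g) {
  R_xlen_t n = x.size();
  NumericVector d(n);
  const double* xr = REAL(x);
  const double* gr = REAL(g);
  double* dr = REAL(d);
  for (R_xlen_t i = 0; i < n; ++i) dr[i] = xr[i] > 0.0 ? gr[i] : 0.0;
  d.attr("dim") = x.attr("dim");
  return d;
}

// 1x1 stride-1 ungrouped convolution: a pure channel-mixing GEMM on
// zero-copy views of the (HW, C) sample slices. No im2col, double precision.

// [[Rcpp::export]]
NumericVector cpp_conv1x1_fwd(NumericVector x, IntegerVector xd,
                              NumericVector w, NumericVector b) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = w.size() / C;
  const size_t P = (size_t)H * W;
  const bool has_bias = b.size() > 0;
  NumericVector y(P * Cout * (size_t)N);
  const arma::mat Wm(const_cast<double*>(REAL(w)), C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const arma::mat Xv(const_cast<double*>(REAL(x)) + P * C * (size_t)n,
                       P, C, false, true);
    arma::mat Yv(REAL(y) + P * Cout * (size_t)n, P, Cout, false, true);
    Yv = Xv * Wm;
  }
  if (has_bias) {
    double* yr = REAL(y);
    for (int n = 0; n < N; ++n) {
      for (int co = 0; co < Cout; ++co) {
        double* yp = yr + P * ((size_t)co + (size_t)Cout * n);
        const double bb = b[co];
        for (size_t i = 0; i < P; ++i) yp[i] += bb;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv1x1_bwd(NumericVector x, IntegerVector xd,
                     NumericVector w, NumericVector dy,
                     bool need_dx, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = w.size() / C;
  const size_t P = (size_t)H * W;
  const arma::mat Wm(const_cast<double*>(REAL(w)), C, Cout, false, true);
  arma::mat dWm(C, Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? P * C * (size_t)N : 0);
  NumericVector db(has_bias ? Cout : 0);
  for (int n = 0; n < N; ++n) {
    const arma::mat Xv(const_cast<double*>(REAL(x)) + P * C * (size_t)n,
                       P, C, false, true);
    const arma::mat dYv(const_cast<double*>(REAL(dy)) + P * Cout * (size_t)n,
                        P, Cout, false, true);
    dWm += Xv.t() * dYv;
    if (need_dx) {
      arma::mat dXv(REAL(dx) + P * C * (size_t)n, P, C, false, true);
      dXv = dYv * Wm.t();
    }
    if (has_bias) {
      for (int co = 0; co < Cout; ++co) {
        double s = 0.0;
        const double* dyc = REAL(dy) + P * ((size_t)co + (size_t)Cout * n);
        for (size_t i = 0; i < P; ++i) s += dyc[i];
        db[co] += s;
      }
    }
  }
  NumericVector dw(w.size());
  std::copy(dWm.memptr(), dWm.memptr() + w.size(), REAL(dw));
  dw.attr("dim") = IntegerVector::create(1, 1, C, Cout);
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
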