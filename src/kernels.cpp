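// Tensor kernels for the segmentation engine.
//
// Feature maps are dense double arrays with dim (C, H, W, N): channel
// fastest, so per-channel broadcasts on the R side are plain vector
// recycling and the innermost loops here are contiguous.
//
// Every forward kernel has a matching hand-derived backward; the test
// suite checks all of them against central finite differences.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::uword oidx(int c, int i, int j, int n,
                               int C, int H, int W) {
  return (arma::uword)c + (arma::uword)C * (i + (arma::uword)H * (j + (arma::uword)W * n));
}

// im2col for one sample: rows ordered (c, ki, kj), cols ordered (i, j).
static void im2col(const double* x, int C, int H, int W,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, arma::mat& col) {
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const arma::uword ccol = (arma::uword)i + (arma::uword)Ho * j;
      double* dst = col.colptr(ccol);
      for (int kj = 0; kj < kw; ++kj) {
        const int sj = j * stride + kj - pw;
        for (int ki = 0; ki < kh; ++ki) {
          const int si = i * stride + ki - ph;
          double* d = dst + (arma::uword)C * (ki + (arma::uword)kh * kj);
          if (si < 0 || si >= H || sj < 0 || sj >= W) {
            std::fill(d, d + C, 0.0);
          } else {
            const double* s = x + (arma::uword)C * (si + (arma::uword)H * sj);
            std::copy(s, s + C, d);
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int C, int H, int W,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, double* dx) {
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const arma::uword ccol = (arma::uword)i + (arma::uword)Ho * j;
      const double* src = col.colptr(ccol);
      for (int kj = 0; kj < kw; ++kj) {
        const int sj = j * stride + kj - pw;
        if (sj < 0 || sj >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int si = i * stride + ki - ph;
          if (si < 0 || si >= H) continue;
          const double* s = src + (arma::uword)C * (ki + (arma::uword)kh * kj);
          double* d = dx + (arma::uword)C * (si + (arma::uword)H * sj);
          for (int c = 0; c < C; ++c) d[c] += s[c];
        }
      }
    }
  }
}

// Full convolution, weight matrix (C*kh*kw) x Cout, "same"-style padding
// supplied by the caller.
// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericMatrix wmat, int kh, int kw,
                             int stride, int ph, int pw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  const int Cout = wmat.ncol();
  const arma::mat wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false);
  NumericVector y((R_xlen_t)Cout * Ho * Wo * N);
  if (kh == 1 && kw == 1 && stride == 1) {
    // pointwise fast path: one GEMM over all positions and samples
    const arma::mat xm(const_cast<double*>(x.begin()), C,
                       (arma::uword)H * W * N, false, true);
    arma::mat ym(y.begin(), Cout, (arma::uword)H * W * N, false, true);
    ym = wm.t() * xm;
    y.attr("dim") = IntegerVector::create(Cout, H, W, N);
    return y;
  }
  arma::mat col((arma::uword)C * kh * kw, (arma::uword)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)C * H * W * n, C, H, W, kh, kw,
           stride, ph, pw, Ho, Wo, col);
    arma::mat yn(y.begin() + (R_xlen_t)Cout * Ho * Wo * n,
                 Cout, (arma::uword)Ho * Wo, false, true);
    yn = wm.t() * col;
  }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector dims,
                    NumericMatrix wmat, NumericVector dy,
                    int kh, int kw, int stride, int ph, int pw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  const int Cout = wmat.ncol();
  const arma::mat wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false);
  NumericVector dx((R_xlen_t)C * H * W * N);
  NumericMatrix dwm(wmat.nrow(), wmat.ncol());
  arma::mat dwa(dwm.begin(), dwm.nrow(), dwm.ncol(), false);
  if (kh == 1 && kw == 1 && stride == 1) {
    const arma::mat xm(const_cast<double*>(x.begin()), C,
                       (arma::uword)H * W * N, false, true);
    const arma::mat dym(const_cast<double*>(dy.begin()), Cout,
                        (arma::uword)H * W * N, false, true);
    dwa = xm * dym.t();
    arma::mat dxm(dx.begin(), C, (arma::uword)H * W * N, false, true);
    dxm = wm * dym;
    dx.attr("dim") = dims;
    return List::create(_["dx"] = dx, _["dw"] = dwm);
  }
  arma::mat col((arma::uword)C * kh * kw, (arma::uword)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)C * H * W * n;
    im2col(xn, C, H, W, kh, kw, stride, ph, pw, Ho, Wo, col);
    const arma::mat dyn(const_cast<double*>(dy.begin()) + (R_xlen_t)Cout * Ho * Wo * n,
                        Cout, (arma::uword)Ho * Wo, false, true);
    dwa += col * dyn.t();
    arma::mat dcol = wm * dyn;
    col2im(dcol, C, H, W, kh, kw, stride, ph, pw, Ho, Wo,
           dx.begin() + (R_xlen_t)C * H * W * n);
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dw"] = dwm);
}

// Depthwise convolution, stride 1, "same" padding, kernel (C, kh, kw).
// [[Rcpp::export(name = ".dwconv_fwd_cpp")]]
NumericVector dwconv_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericVector w, int kh, int kw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((R_xlen_t)C * H * W * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)C * H * W * n;
    double* yn = y.begin() + (R_xlen_t)C * H * W * n;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* wk = w.begin() + (R_xlen_t)C * (ki + kh * kj);
        const int i0 = std::max(0, ph - ki), i1 = std::min(H, H + ph - ki);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          const double* xcol = xn + (arma::uword)C * ((i0 + ki - ph) + (arma::uword)H * sj);
          double* ycol = yn + (arma::uword)C * (i0 + (arma::uword)H * j);
          for (int i = i0; i < i1; ++i) {
            for (int c = 0; c < C; ++c) ycol[c] += wk[c] * xcol[c];
            xcol += C; ycol += C;
          }
        }
      }
    }
  }
  y.attr("dim") = dims;
  return y;
}

// [[Rcpp::export(name = ".dwconv_bwd_cpp")]]
List dwconv_bwd_cpp(NumericVector x, IntegerVector dims,
                    NumericVector w, NumericVector dy, int kh, int kw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dx((R_xlen_t)C * H * W * N);
  NumericVector dw((R_xlen_t)C * kh * kw);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)C * H * W * n;
    const double* dyn = dy.begin() + (R_xlen_t)C * H * W * n;
    double* dxn = dx.begin() + (R_xlen_t)C * H * W * n;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* wk = w.begin() + (R_xlen_t)C * (ki + kh * kj);
        double* dwk = dw.begin() + (R_xlen_t)C * (ki + kh * kj);
        const int i0 = std::max(0, ph - ki), i1 = std::min(H, H + ph - ki);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          const double* xcol = xn + (arma::uword)C * ((i0 + ki - ph) + (arma::uword)H * sj);
          double* dxcol = dxn + (arma::uword)C * ((i0 + ki - ph) + (arma::uword)H * sj);
          const double* gcol = dyn + (arma::uword)C * (i0 + (arma::uword)H * j);
          for (int i = i0; i < i1; ++i) {
            for (int c = 0; c < C; ++c) {
              dwk[c] += gcol[c] * xcol[c];
              dxcol[c] += gcol[c] * wk[c];
            }
            xcol += C; dxcol += C; gcol += C;
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  dw.attr("dim") = IntegerVector::create(C, kh, kw);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 max pooling (stride 2); returns pooled map and argmax offsets.
// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  IntegerVector amax((R_xlen_t)C * Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int barg = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const double v = x[oidx(c, 2 * i + di, 2 * j + dj, n, C, H, W)];
              if (v > best) { best = v; barg = di + 2 * dj; }
            }
          }
          const arma::uword o = oidx(c, i, j, n, C, Ho, Wo);
          y[o] = best; amax[o] = barg;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector amax,
                               IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)C * H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        for (int c = 0; c < C; ++c) {
          const arma::uword o = oidx(c, i, j, n, C, Ho, Wo);
          const int a = amax[o];
          dx[oidx(c, 2 * i + a % 2, 2 * j + a / 2, n, C, H, W)] += dy[o];
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Bilinear x2 upsampling, half-pixel-centre convention (output pixel i
// samples input coordinate (i + 0.5)/2 - 0.5, edges clamped).
static void up2_weights(int Ho, int H, std::vector<int>& s0,
                        std::vector<int>& s1, std::vector<double>& w0) {
  s0.resize(Ho); s1.resize(Ho); w0.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(src);
    double t = src - f;
    int a = std::min(std::max(f, 0), H - 1);
    int b = std::min(std::max(f + 1, 0), H - 1);
    s0[i] = a; s1[i] = b; w0[i] = 1.0 - t;
  }
}

// [[Rcpp::export(name = ".bilinear_up2_fwd_cpp")]]
NumericVector bilinear_up2_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  up2_weights(Ho, H, ri0, ri1, rw);
  up2_weights(Wo, W, cj0, cj1, cw);
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)C * H * W * n;
    double* yn = y.begin() + (R_xlen_t)C * Ho * Wo * n;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double w00 = rw[i] * cw[j], w10 = (1 - rw[i]) * cw[j];
        const double w01 = rw[i] * (1 - cw[j]), w11 = (1 - rw[i]) * (1 - cw[j]);
        const double* p00 = xn + (arma::uword)C * (ri0[i] + (arma::uword)H * cj0[j]);
        const double* p10 = xn + (arma::uword)C * (ri1[i] + (arma::uword)H * cj0[j]);
        const double* p01 = xn + (arma::uword)C * (ri0[i] + (arma::uword)H * cj1[j]);
        const double* p11 = xn + (arma::uword)C * (ri1[i] + (arma::uword)H * cj1[j]);
        double* yp = yn + (arma::uword)C * (i + (arma::uword)Ho * j);
        for (int c = 0; c < C; ++c)
          yp[c] = w00 * p00[c] + w10 * p10[c] + w01 * p01[c] + w11 * p11[c];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".bilinear_up2_bwd_cpp")]]
NumericVector bilinear_up2_bwd_cpp(NumericVector dy, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  up2_weights(Ho, H, ri0, ri1, rw);
  up2_weights(Wo, W, cj0, cj1, cw);
  NumericVector dx((R_xlen_t)C * H * W * N);
  for (int n = 0; n < N; ++n) {
    const double* gn = dy.begin() + (R_xlen_t)C * Ho * Wo * n;
    double* dxn = dx.begin() + (R_xlen_t)C * H * W * n;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double w00 = rw[i] * cw[j], w10 = (1 - rw[i]) * cw[j];
        const double w01 = rw[i] * (1 - cw[j]), w11 = (1 - rw[i]) * (1 - cw[j]);
        const double* gp = gn + (arma::uword)C * (i + (arma::uword)Ho * j);
        double* p00 = dxn + (arma::uword)C * (ri0[i] + (arma::uword)H * cj0[j]);
        double* p10 = dxn + (arma::uword)C * (ri1[i] + (arma::uword)H * cj0[j]);
        double* p01 = dxn + (arma::uword)C * (ri0[i] + (arma::uword)H * cj1[j]);
        double* p11 = dxn + (arma::uword)C * (ri1[i] + (arma::uword)H * cj1[j]);
        for (int c = 0; c < C; ++c) {
          p00[c] += w00 * gp[c]; p10[c] += w10 * gp[c];
          p01[c] += w01 * gp[c]; p11[c] += w11 * gp[c];
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Batch norm over (H, W, N) per channel, single pass for the statistics.
// training: batch statistics (and xhat cache); eval: supplied running stats.
// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(NumericVector x, IntegerVector dims, NumericVector gamma,
                NumericVector beta, NumericVector rmean, NumericVector rvar,
                bool training, double eps) {
  const int C = dims[0];
  const R_xlen_t M = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericVector mu(C), va(C);
  if (training) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    const double* xp = x.begin();
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* col = xp + (R_xlen_t)C * m;
      for (int c = 0; c < C; ++c) { s1[c] += col[c]; s2[c] += col[c] * col[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / M;
      va[c] = s2[c] / M - mu[c] * mu[c];
    }
  } else {
    mu = rmean; va = rvar;
  }
  NumericVector y(x.size()), xhat(x.size()), inv_sd(C);
  for (int c = 0; c < C; ++c) inv_sd[c] = 1.0 / std::sqrt(va[c] + eps);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* col = xp + (R_xlen_t)C * m;
    double* yc = yp + (R_xlen_t)C * m;
    double* hc = hp + (R_xlen_t)C * m;
    for (int c = 0; c < C; ++c) {
      hc[c] = (col[c] - mu[c]) * inv_sd[c];
      yc[c] = hc[c] * gamma[c] + beta[c];
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd,
                      _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector xhat, NumericVector inv_sd,
                NumericVector gamma, NumericVector dy, IntegerVector dims,
                bool training) {
  const int C = dims[0];
  const R_xlen_t M = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> sdx(C, 0.0), sdxh(C, 0.0);
  const double* hp = xhat.begin();
  const double* gp = dy.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* hc = hp + (R_xlen_t)C * m;
    const double* gc = gp + (R_xlen_t)C * m;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += gc[c] * hc[c];
      dbeta[c] += gc[c];
    }
  }
  NumericVector dx(dy.size());
  double* dp = dx.begin();
  if (training) {
    for (int c = 0; c < C; ++c) {
      sdx[c] = dbeta[c] * gamma[c] / M;     // mean of dxhat
      sdxh[c] = dgamma[c] * gamma[c] / M;   // mean of dxhat * xhat
    }
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* hc = hp + (R_xlen_t)C * m;
      const double* gc = gp + (R_xlen_t)C * m;
      double* dc = dp + (R_xlen_t)C * m;
      for (int c = 0; c < C; ++c)
        dc[c] = (gc[c] * gamma[c] - sdx[c] - hc[c] * sdxh[c]) * inv_sd[c];
    }
  } else {
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* gc = gp + (R_xlen_t)C * m;
      double* dc = dp + (R_xlen_t)C * m;
      for (int c = 0; c < C; ++c) dc[c] = gc[c] * gamma[c] * inv_sd[c];
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// backward keyed on the forward output (y > 0 iff x > 0)
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  const double* yp = y.begin();
  const double* gp = dy.begin();
  double* dp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[i] = yp[i] > 0 ? gp[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
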