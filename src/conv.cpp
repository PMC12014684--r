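// Grouped 2-D convolution kernels (im2col + GEMM) for the autodiff tape.
//
// Tensor layout is column-major R arrays with dim (C, H, W, N): channel is
// the fastest-varying index, batch the slowest.  Padding is always "same"
// for odd kernels: pad = (K - 1) / 2, so Hout = ceil(H / stride).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Fill the im2col patch matrix for one image and one channel group.
// P has dim (Cpg*K*K, Ho*Wo); column q = oh + Ho*ow.
static void im2col_group(const double* x, int C, int H, int W,
                         int c0, int Cpg, int K, int stride, int pad,
                         int Ho, int Wo, arma::mat& P) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int q = oh + Ho * ow;
      double* col = P.colptr(q);
      for (int kw = 0; kw < K; ++kw) {
        const int iw = ow * stride - pad + kw;
        for (int kh = 0; kh < K; ++kh) {
          const int ih = oh * stride - pad + kh;
          double* dst = col + Cpg * (kh + K * kw);
          if (ih < 0 || ih >= H || iw < 0 || iw >= W) {
            for (int c = 0; c < Cpg; ++c) dst[c] = 0.0;
          } else {
            const double* src = x + (c0 + C * (ih + H * (size_t)iw));
            for (int c = 0; c < Cpg; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-gradient matrix back onto the input gradient.
static void col2im_group(const arma::mat& GP, double* gx, int C, int H, int W,
                         int c0, int Cpg, int K, int stride, int pad,
                         int Ho, int Wo) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int q = oh + Ho * ow;
      const double* col = GP.colptr(q);
      for (int kw = 0; kw < K; ++kw) {
        const int iw = ow * stride - pad + kw;
        if (iw < 0 || iw >= W) continue;
        for (int kh = 0; kh < K; ++kh) {
          const int ih = oh * stride - pad + kh;
          if (ih < 0 || ih >= H) continue;
          const double* src = col + Cpg * (kh + K * kw);
          double* dst = gx + (c0 + C * (ih + H * (size_t)iw));
          for (int c = 0; c < Cpg; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// Rearrange the weight array (Cout, Cpg, K, K) into one GEMM matrix per
// group: rows = output channels of the group, cols = Cpg*K*K patch entries.
static arma::mat weight_matrix(const double* w, int Cout, int Cpg, int K,
                               int g, int Coutpg) {
  arma::mat Wm(Coutpg, Cpg * K * K);
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int c = 0; c < Cpg; ++c) {
        const size_t widx = (size_t)Cout * (c + Cpg * (kh + K * (size_t)kw));
        const int col = c + Cpg * (kh + K * kw);
        for (int co = 0; co < Coutpg; ++co)
          Wm(co, col) = w[g * Coutpg + co + widx];
      }
  return Wm;
}

// Direct loops for the depthwise case (groups == C, one kernel per
// channel): the per-group GEMM formulation degenerates to C tiny products
// and its overhead dominates, so this path skips im2col entirely.
static void depthwise_fwd(const double* x, const double* w, double* y,
                          int C, int H, int W, int N, int K, int stride,
                          int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)C * H * W * n;
    double* yn = y + (size_t)C * Ho * Wo * n;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        double* yp = yn + (size_t)C * (oh + Ho * (size_t)ow);
        for (int kw = 0; kw < K; ++kw) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const double* xp = xn + (size_t)C * (ih + H * (size_t)iw);
            const double* wp = w + (size_t)C * (kh + K * (size_t)kw);
            for (int c = 0; c < C; ++c) yp[c] += xp[c] * wp[c];
          }
        }
      }
  }
}

static void depthwise_bwd(const double* x, const double* w, const double* gy,
                          double* gx, double* gw,
                          int C, int H, int W, int N, int K, int stride,
                          int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)C * H * W * n;
    double* gxn = gx + (size_t)C * H * W * n;
    const double* gyn = gy + (size_t)C * Ho * Wo * n;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const double* gp = gyn + (size_t)C * (oh + Ho * (size_t)ow);
        for (int kw = 0; kw < K; ++kw) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const double* xp = xn + (size_t)C * (ih + H * (size_t)iw);
            double* gxp = gxn + (size_t)C * (ih + H * (size_t)iw);
            double* gwp = gw + (size_t)C * (kh + K * (size_t)kw);
            const double* wp = w + (size_t)C * (kh + K * (size_t)kw);
            for (int c = 0; c < C; ++c) {
              gxp[c] += gp[c] * wp[c];
              gwp[c] += gp[c] * xp[c];
            }
          }
        }
      }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias,
                         int stride, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd.size() > 3 ? xd[3] : 1;
  const int Cout = wd[0], Cpg = wd[1], K = wd[2];
  if (C != Cpg * groups) stop("input channels (%d) != groups (%d) x per-group channels (%d)", C, groups, Cpg);
  if (Cout % groups != 0) stop("out_channels must be divisible by groups");
  const int pad = (K - 1) / 2;
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  const int Coutpg = Cout / groups;

  NumericVector y(static_cast<R_xlen_t>(Cout) * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);

  if (K == 1 && groups == 1 && stride == 1) {
    // pointwise: one GEMM over all cells, no patch copy
    arma::mat Wm(const_cast<double*>(w.begin()), Cout, C, false, true);
    arma::mat Xm(const_cast<double*>(x.begin()), C,
                 (size_t)H * W * N, false, true);
    arma::mat Ym(y.begin(), Cout, (size_t)H * W * N, false, true);
    Ym = Wm * Xm;
  } else if (groups == C && Cpg == 1 && Cout == C) {
    depthwise_fwd(x.begin(), w.begin(), y.begin(), C, H, W, N, K, stride,
                  pad, Ho, Wo);
  }
  if ((K == 1 && groups == 1 && stride == 1) ||
      (groups == C && Cpg == 1 && Cout == C)) {
    if (bias.isNotNull()) {
      NumericVector b(bias);
      double* yp = y.begin();
      const R_xlen_t cells = (R_xlen_t)Ho * Wo * N;
      for (R_xlen_t q = 0; q < cells; ++q)
        for (int co = 0; co < Cout; ++co) yp[co + (size_t)Cout * q] += b[co];
    }
    return y;
  }

  std::vector<arma::mat> Wms;
  Wms.reserve(groups);
  for (int g = 0; g < groups; ++g)
    Wms.push_back(weight_matrix(w.begin(), Cout, Cpg, K, g, Coutpg));

  arma::mat P(Cpg * K * K, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)C * H * W * n;
    // y for image n viewed as (Cout x Ho*Wo)
    arma::mat Yn(y.begin() + (size_t)Cout * Ho * Wo * n, Cout, Ho * Wo,
                 false, true);
    for (int g = 0; g < groups; ++g) {
      im2col_group(xn, C, H, W, g * Cpg, Cpg, K, stride, pad, Ho, Wo, P);
      Yn.rows(g * Coutpg, (g + 1) * Coutpg - 1) = Wms[g] * P;
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    double* yp = y.begin();
    const R_xlen_t cells = (R_xlen_t)Ho * Wo * N;
    for (R_xlen_t q = 0; q < cells; ++q)
      for (int co = 0; co < Cout; ++co) yp[co + (size_t)Cout * q] += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd.size() > 3 ? xd[3] : 1;
  const int Cout = wd[0], Cpg = wd[1], K = wd[2];
  const int pad = (K - 1) / 2;
  const int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  const int Coutpg = Cout / groups;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;

  if ((K == 1 && groups == 1 && stride == 1) ||
      (groups == C && Cpg == 1 && Cout == C)) {
    if (K == 1 && groups == 1 && stride == 1) {
      arma::mat Wm(const_cast<double*>(w.begin()), Cout, C, false, true);
      arma::mat Xm(const_cast<double*>(x.begin()), C,
                   (size_t)H * W * N, false, true);
      arma::mat Gy(const_cast<double*>(gy.begin()), Cout,
                   (size_t)H * W * N, false, true);
      arma::mat GW(gw.begin(), Cout, C, false, true);
      arma::mat GX(gx.begin(), C, (size_t)H * W * N, false, true);
      GW = Gy * Xm.t();
      GX = Wm.t() * Gy;
    } else {
      depthwise_bwd(x.begin(), w.begin(), gy.begin(), gx.begin(), gw.begin(),
                    C, H, W, N, K, stride, pad, Ho, Wo);
    }
    List out = List::create(Named("gx") = gx, Named("gw") = gw);
    if (has_bias) {
      NumericVector gb(Cout);
      const double* gp = gy.begin();
      const R_xlen_t cells = (R_xlen_t)Ho * Wo * N;
      for (R_xlen_t q = 0; q < cells; ++q)
        for (int co = 0; co < Cout; ++co) gb[co] += gp[co + (size_t)Cout * q];
      out["gb"] = gb;
    }
    return out;
  }

  std::vector<arma::mat> Wms, GWms;
  for (int g = 0; g < groups; ++g) {
    Wms.push_back(weight_matrix(w.begin(), Cout, Cpg, K, g, Coutpg));
    GWms.push_back(arma::mat(Coutpg, Cpg * K * K, arma::fill::zeros));
  }

  arma::mat P(Cpg * K * K, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)C * H * W * n;
    double* gxn = gx.begin() + (size_t)C * H * W * n;
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)Cout * Ho * Wo * n,
                 Cout, Ho * Wo, false, true);
    for (int g = 0; g < groups; ++g) {
      im2col_group(xn, C, H, W, g * Cpg, Cpg, K, stride, pad, Ho, Wo, P);
      arma::mat Gg = Gy.rows(g * Coutpg, (g + 1) * Coutpg - 1);
      GWms[g] += Gg * P.t();
      arma::mat GP = Wms[g].t() * Gg;
      col2im_group(GP, gxn, C, H, W, g * Cpg, Cpg, K, stride, pad, Ho, Wo);
    }
  }

  // scatter GWms back into the (Cout, Cpg, K, K) layout
  for (int g = 0; g < groups; ++g)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh)
        for (int c = 0; c < Cpg; ++c) {
          const size_t widx = (size_t)Cout * (c + Cpg * (kh + K * (size_t)kw));
          const int col = c + Cpg * (kh + K * kw);
          for (int co = 0; co < Coutpg; ++co)
            gw[g * Coutpg + co + widx] = GWms[g](co, col);
        }

  List out = List::create(Named("gx") = gx, Named("gw") = gw);
  if (has_bias) {
    NumericVector gb(Cout);
    const double* gp = gy.begin();
    const R_xlen_t cells = (R_xlen_t)Ho * Wo * N;
    for (R_xlen_t q = 0; q < cells; ++q)
      for (int co = 0; co < Cout; ++co) gb[co] += gp[co + (size_t)Cout * q];
    out["gb"] = gb;
  }
  return out;
}

// [[Rcpp::export(name = ".hswish_fwd")]]
NumericVector hswish_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = xp[i];
    const double r = v + 3.0 < 0.0 ? 0.0 : (v + 3.0 > 6.0 ? 6.0 : v + 3.0);
    yp[i] = v * r / 6.0;
  }
  return y;
}

// [[Rcpp::export(name = ".hswish_bwd")]]
NumericVector hswish_bwd(NumericVector x, NumericVector gy) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* op = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = xp[i];
    const double d = v >= 3.0 ? 1.0 : (v <= -3.0 ? 0.0 : (2.0 * v + 3.0) / 6.0);
    op[i] = gp[i] * d;
  }
  return gx;
}

// channel-wise sums/means over a (C, ...) array without reshaping
// [[Rcpp::export(name = ".chan_sums")]]
NumericVector chan_sums(NumericVector x, int C) {
  NumericVector out(C);
  double* op = out.begin();
  const double* xp = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) op[c] += xp[i];
  }
  return out;
}

// [[Rcpp::export(name = ".chan_means")]]
NumericVector chan_means(NumericVector x, int C) {
  NumericVector out = chan_sums(x, C);
  const double m = (double)(x.size() / C);
  for (int c = 0; c < C; ++c) out[c] /= m;
  return out;
}

// fused batch-norm forward: y = gamma * (x - mu) * istd + beta, channel
// fastest
// [[Rcpp::export(name = ".bn_fwd")]]
NumericVector bn_fwd(NumericVector x, NumericVector gamma,
                     NumericVector beta, NumericVector mu,
                     NumericVector istd) {
  const int C = gamma.size();
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* gp = gamma.begin();
  const double* bp = beta.begin();
  const double* mp = mu.begin();
  const double* ip = istd.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i)
      yp[i] = gp[c] * (xp[i] - mp[c]) * ip[c] + bp[c];
  }
  return y;
}

// per-channel mean and biased variance in one pass
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x, int C) {
  std::vector<double> s(C, 0.0), s2(C, 0.0);
  const double* xp = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) {
      s[c] += xp[i];
      s2[c] += xp[i] * xp[i];
    }
  }
  const double m = (double)(n / C);
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = s[c] / m;
    var[c] = s2[c] / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(Named("mean") = mu, Named("var") = var);
}

// fused batch-norm backward; training mode differentiates through the
// batch statistics
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector g, NumericVector gamma,
            NumericVector mu, NumericVector istd, bool training) {
  const int C = gamma.size();
  const R_xlen_t n = x.size();
  const double m = (double)(n / C);
  NumericVector ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gp = g.begin();
  const double* gam = gamma.begin();
  const double* mp = mu.begin();
  const double* ip = istd.begin();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) {
      ggamma[c] += gp[i] * (xp[i] - mp[c]) * ip[c];
      gbeta[c] += gp[i];
    }
  }
  NumericVector gx(n);
  gx.attr("dim") = x.attr("dim");
  double* op = gx.begin();
  if (training) {
    for (R_xlen_t i = 0; i < n; ) {
      for (int c = 0; c < C; ++c, ++i) {
        const double xhat = (xp[i] - mp[c]) * ip[c];
        op[i] = ip[c] * gam[c] *
          (gp[i] - gbeta[c] / m - xhat * ggamma[c] / m);
      }
    }
  } else {
    for (R_xlen_t i = 0; i < n; ) {
      for (int c = 0; c < C; ++c, ++i)
        op[i] = gp[i] * gam[c] * ip[c];
    }
  }
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}
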