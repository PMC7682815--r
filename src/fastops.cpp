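#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam/AMSGrad update, in place on the weight and moment arrays.
// Callers own these arrays exclusively (they are deep-copied when a model
// enters training and when best-epoch snapshots are taken), so bypassing
// R's copy-on-write here is safe and removes ~10 full-array temporaries
// per update. Raw restrict pointers let the compiler vectorize the
// sqrt/divide chain, which dominates the cost.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector w, NumericVector g, NumericVector m,
                   NumericVector v, NumericVector vhat,
                   double lr, double beta1, double beta2, double eps,
                   double t, bool amsgrad) {
  R_xlen_t n = w.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("cpp_adam_step: length mismatch");
  const double c1 = 1.0 - std::pow(beta1, t);
  const double inv_sqrt_c2 = 1.0 / std::sqrt(1.0 - std::pow(beta2, t));
  const double scale = lr / c1;
  const double a1 = 1.0 - beta1, a2 = 1.0 - beta2;
  double *__restrict wp = w.begin();
  const double *__restrict gp = g.begin();
  double *__restrict mp = m.begin();
  double *__restrict vp = v.begin();
  if (amsgrad) {
    double *__restrict hp = vhat.begin();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = gp[i];
      const double mi = beta1 * mp[i] + a1 * gi;
      const double vi = beta2 * vp[i] + a2 * gi * gi;
      mp[i] = mi;
      vp[i] = vi;
      if (vi > hp[i]) hp[i] = vi;
      wp[i] -= scale * mi / (std::sqrt(hp[i]) * inv_sqrt_c2 + eps);
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = gp[i];
      const double mi = beta1 * mp[i] + a1 * gi;
      const double vi = beta2 * vp[i] + a2 * gi * gi;
      mp[i] = mi;
      vp[i] = vi;
      wp[i] -= scale * mi / (std::sqrt(vi) * inv_sqrt_c2 + eps);
    }
  }
}

// In-place column-wise bias add on a freshly allocated matmul result.
// [[Rcpp::export]]
void cpp_add_bias(NumericMatrix y, NumericVector b) {
  int nr = y.nrow(), nc = y.ncol();
  if (b.size() != nc) stop("cpp_add_bias: bias length mismatch");
  double *__restrict yp = y.begin();
  const double *__restrict bp = b.begin();
  for (int j = 0; j < nc; ++j) {
    const double bj = bp[j];
    double *__restrict col = yp + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
}

// im2col for kernel-3 "same" 1D convolution over (n, L, C) column-major
// arrays: output matrix (n*L, 3*C), block j holding the input shifted by
// j-1 positions (zero padded).
// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(NumericVector x, int n, int L, int C) {
  NumericMatrix M(n * L, 3 * C);
  const double *xp = x.begin();
  double *mp = M.begin();
  const R_xlen_t rows = (R_xlen_t)n * L;
  for (int j = 0; j < 3; ++j) {      // kernel offset: input pos = t + j - 1
    for (int c = 0; c < C; ++c) {
      double *out = mp + ((R_xlen_t)(j * C + c)) * rows;
      const double *in = xp + (R_xlen_t)c * n * L;
      for (int t = 0; t < L; ++t) {
        const int src = t + j - 1;
        double *o = out + (R_xlen_t)t * n;
        if (src < 0 || src >= L) {
          for (int i = 0; i < n; ++i) o[i] = 0.0;
        } else {
          const double *s = in + (R_xlen_t)src * n;
          for (int i = 0; i < n; ++i) o[i] = s[i];
        }
      }
    }
  }
  return M;
}

// Scatter-add inverse of cpp_im2col1d: dM (n*L, 3*C) -> dX (n, L, C).
// [[Rcpp::export]]
NumericVector cpp_col2im1d(NumericMatrix dM, int n, int L, int C) {
  NumericVector dX((R_xlen_t)n * L * C);
  double *dxp = dX.begin();
  const double *mp = dM.begin();
  const R_xlen_t rows = (R_xlen_t)n * L;
  for (int j = 0; j < 3; ++j) {
    for (int c = 0; c < C; ++c) {
      const double *in = mp + ((R_xlen_t)(j * C + c)) * rows;
      double *out = dxp + (R_xlen_t)c * n * L;
      for (int t = 0; t < L; ++t) {
        const int dst = t + j - 1;
        if (dst < 0 || dst >= L) continue;
        const double *s = in + (R_xlen_t)t * n;
        double *o = out + (R_xlen_t)dst * n;
        for (int i = 0; i < n; ++i) o[i] += s[i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, L, C);
  return dX;
}

// Max pooling window 2 stride 2 on (n, L, C); returns pooled array and the
// first-wins argmax mask.
// [[Rcpp::export]]
List cpp_maxpool1d(NumericVector x, int n, int L, int C) {
  const int Lo = L / 2;
  NumericVector y((R_xlen_t)n * Lo * C);
  LogicalVector maskA((R_xlen_t)n * Lo * C);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = maskA.begin();
  for (int c = 0; c < C; ++c) {
    const double *in = xp + (R_xlen_t)c * n * L;
    double *out = yp + (R_xlen_t)c * n * Lo;
    int *am = ap + (R_xlen_t)c * n * Lo;
    for (int t = 0; t < Lo; ++t) {
      const double *a = in + (R_xlen_t)(2 * t) * n;
      const double *b = in + (R_xlen_t)(2 * t + 1) * n;
      double *o = out + (R_xlen_t)t * n;
      int *m = am + (R_xlen_t)t * n;
      for (int i = 0; i < n; ++i) {
        const bool ge = a[i] >= b[i];
        o[i] = ge ? a[i] : b[i];
        m[i] = ge;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(n, Lo, C);
  maskA.attr("dim") = IntegerVector::create(n, Lo, C);
  return List::create(_["Y"] = y, _["maskA"] = maskA);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool1d_bwd(NumericVector dY, LogicalVector maskA,
                                int n, int L, int C) {
  const int Lo = L / 2;
  NumericVector dX((R_xlen_t)n * L * C);
  const double *dyp = dY.begin();
  const int *ap = maskA.begin();
  double *dxp = dX.begin();
  for (int c = 0; c < C; ++c) {
    const double *in = dyp + (R_xlen_t)c * n * Lo;
    const int *am = ap + (R_xlen_t)c * n * Lo;
    double *out = dxp + (R_xlen_t)c * n * L;
    for (int t = 0; t < Lo; ++t) {
      const double *g = in + (R_xlen_t)t * n;
      const int *m = am + (R_xlen_t)t * n;
      double *oa = out + (R_xlen_t)(2 * t) * n;
      double *ob = out + (R_xlen_t)(2 * t + 1) * n;
      for (int i = 0; i < n; ++i) {
        if (m[i]) oa[i] = g[i]; else ob[i] = g[i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, L, C);
  return dX;
}

// ReLU forward returning activations and positive mask in one pass.
// [[Rcpp::export]]
List cpp_relu(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  LogicalVector pos(n);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *pp = pos.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool p = xp[i] > 0;
    yp[i] = p ? xp[i] : 0.0;
    pp[i] = p;
  }
  if (x.hasAttribute("dim")) {
    y.attr("dim") = x.attr("dim");
    pos.attr("dim") = x.attr("dim");
  }
  return List::create(_["Y"] = y, _["pos"] = pos);
}

// Inverted dropout using R's RNG stream (identical to runif()-based masks
// under the same seed). Returns the dropped activations and the scaled mask.
// [[Rcpp::export]]
List cpp_dropout(NumericVector x, double rate) {
  R_xlen_t n = x.size();
  NumericVector y(n), mask(n);
  const double scale = 1.0 / (1.0 - rate);
  const double *xp = x.begin();
  double *yp = y.begin();
  double *mp = mask.begin();
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double m = (unif_rand() >= rate) ? scale : 0.0;
    mp[i] = m;
    yp[i] = xp[i] * m;
  }
  PutRNGstate();
  if (x.hasAttribute("dim")) {
    y.attr("dim") = x.attr("dim");
    mask.attr("dim") = x.attr("dim");
  }
  return List::create(_["Y"] = y, _["mask"] = mask);
}

// im2col for 3x3 "same" 2D convolution over (n, H, W, C) column-major
// arrays: output (n*H*W, 9*C); block order matches offsets
// (dx, dy) for dx in 0..2, dy in 0..2 with dy fastest, i.e. input cell
// (h + dy - 1, w + dx - 1).
// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector x, int n, int H, int W, int C) {
  const R_xlen_t rows = (R_xlen_t)n * H * W;
  NumericMatrix M(rows, 9 * C);
  const double *xp = x.begin();
  double *mp = M.begin();
  int blk = 0;
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy, ++blk) {
      for (int c = 0; c < C; ++c) {
        double *out = mp + ((R_xlen_t)(blk * C + c)) * rows;
        const double *in = xp + (R_xlen_t)c * n * H * W;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx - 1;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dy - 1;
            double *o = out + (R_xlen_t)(h + (R_xlen_t)H * w) * n;
            if (sw < 0 || sw >= W || sh < 0 || sh >= H) {
              for (int i = 0; i < n; ++i) o[i] = 0.0;
            } else {
              const double *s = in + (R_xlen_t)(sh + (R_xlen_t)H * sw) * n;
              for (int i = 0; i < n; ++i) o[i] = s[i];
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add inverse of cpp_im2col2d: dM (n*H*W, 9*C) -> dX (n, H, W, C).
// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix dM, int n, int H, int W, int C) {
  const R_xlen_t rows = (R_xlen_t)n * H * W;
  NumericVector dX((R_xlen_t)n * H * W * C);
  double *dxp = dX.begin();
  const double *mp = dM.begin();
  int blk = 0;
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy, ++blk) {
      for (int c = 0; c < C; ++c) {
        const double *in = mp + ((R_xlen_t)(blk * C + c)) * rows;
        double *out = dxp + (R_xlen_t)c * n * H * W;
        for (int w = 0; w < W; ++w) {
          const int dw = w + dx - 1;
          if (dw < 0 || dw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int dh = h + dy - 1;
            if (dh < 0 || dh >= H) continue;
            const double *s = in + (R_xlen_t)(h + (R_xlen_t)H * w) * n;
            double *o = out + (R_xlen_t)(dh + (R_xlen_t)H * dw) * n;
            for (int i = 0; i < n; ++i) o[i] += s[i];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, H, W, C);
  return dX;
}

// 2x2 stride-2 max pooling on (n, H, W, C); first-wins argmax index 0..3
// in candidate order (odd,odd), (even,odd), (odd,even), (even,even) -- i.e.
// (2t, 2s), (2t+1, 2s), (2t, 2s+1), (2t+1, 2s+1) in 0-based coordinates.
// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int n, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)n * Ho * Wo * C);
  IntegerVector arg((R_xlen_t)n * Ho * Wo * C);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *gp = arg.begin();
  for (int c = 0; c < C; ++c) {
    const double *in = xp + (R_xlen_t)c * n * H * W;
    double *out = yp + (R_xlen_t)c * n * Ho * Wo;
    int *ag = gp + (R_xlen_t)c * n * Ho * Wo;
    for (int s = 0; s < Wo; ++s) {
      for (int t = 0; t < Ho; ++t) {
        const double *c0 = in + (R_xlen_t)(2 * t + (R_xlen_t)H * (2 * s)) * n;
        const double *c1 = in + (R_xlen_t)(2 * t + 1 + (R_xlen_t)H * (2 * s)) * n;
        const double *c2 = in + (R_xlen_t)(2 * t + (R_xlen_t)H * (2 * s + 1)) * n;
        const double *c3 = in + (R_xlen_t)(2 * t + 1 + (R_xlen_t)H * (2 * s + 1)) * n;
        double *o = out + (R_xlen_t)(t + (R_xlen_t)Ho * s) * n;
        int *g = ag + (R_xlen_t)(t + (R_xlen_t)Ho * s) * n;
        for (int i = 0; i < n; ++i) {
          double best = c0[i]; int idx = 0;
          if (c1[i] > best) { best = c1[i]; idx = 1; }
          if (c2[i] > best) { best = c2[i]; idx = 2; }
          if (c3[i] > best) { best = c3[i]; idx = 3; }
          o[i] = best;
          g[i] = idx;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(n, Ho, Wo, C);
  arg.attr("dim") = IntegerVector::create(n, Ho, Wo, C);
  return List::create(_["Y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d_bwd(NumericVector dY, IntegerVector arg,
                                int n, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dX((R_xlen_t)n * H * W * C);
  const double *dyp = dY.begin();
  const int *gp = arg.begin();
  double *dxp = dX.begin();
  for (int c = 0; c < C; ++c) {
    const double *in = dyp + (R_xlen_t)c * n * Ho * Wo;
    const int *ag = gp + (R_xlen_t)c * n * Ho * Wo;
    double *out = dxp + (R_xlen_t)c * n * H * W;
    for (int s = 0; s < Wo; ++s) {
      for (int t = 0; t < Ho; ++t) {
        const double *g = in + (R_xlen_t)(t + (R_xlen_t)Ho * s) * n;
        const int *a = ag + (R_xlen_t)(t + (R_xlen_t)Ho * s) * n;
        double *o0 = out + (R_xlen_t)(2 * t + (R_xlen_t)H * (2 * s)) * n;
        double *o1 = out + (R_xlen_t)(2 * t + 1 + (R_xlen_t)H * (2 * s)) * n;
        double *o2 = out + (R_xlen_t)(2 * t + (R_xlen_t)H * (2 * s + 1)) * n;
        double *o3 = out + (R_xlen_t)(2 * t + 1 + (R_xlen_t)H * (2 * s + 1)) * n;
        for (int i = 0; i < n; ++i) {
          switch (a[i]) {
            case 0: o0[i] = g[i]; break;
            case 1: o1[i] = g[i]; break;
            case 2: o2[i] = g[i]; break;
            default: o3[i] = g[i];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, H, W, C);
  return dX;
}
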