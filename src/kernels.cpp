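// Low-level array kernels for the autograd engine and instance labelling.
//
// All feature maps are dense double arrays with dim = c(H, W, N, C):
// linear index h + H*(w + W*(n + N*c)). Spatial dims fastest, channels
// slowest, so channel concatenation is contiguous and im2col feeds GEMM
// with position-major rows.

#include <Rcpp.h>
#include <queue>
#include <cfloat>
using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Unfold x (H,W,N,C) into a matrix with rows = outH*outW*N (oh fastest,
// then ow, then n) and cols = kh*kw*C (dh fastest, then dw, then c).
// Out-of-range taps (padding) contribute zeros.
// [[Rcpp::export]]
NumericMatrix k_im2col(NumericVector x, IntegerVector dims,
                       int kh, int kw, int stride, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int oh = out_dim(H, kh, stride, pad), ow = out_dim(W, kw, stride, pad);
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  NumericMatrix M(nrow, (R_xlen_t)kh * kw * C);
  const double* xp = x.begin();
  double* mp = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const R_xlen_t q = dh + (R_xlen_t)kh * (dw + (R_xlen_t)kw * c);
        double* col = mp + q * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xnc = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          for (int j = 0; j < ow; ++j) {
            const int w = j * stride + dw - pad;
            double* dst = col + (R_xlen_t)oh * (j + (R_xlen_t)ow * n);
            if (w < 0 || w >= W) {
              for (int i = 0; i < oh; ++i) dst[i] = 0.0;
            } else {
              const double* src = xnc + (R_xlen_t)H * w;
              for (int i = 0; i < oh; ++i) {
                const int h = i * stride + dh - pad;
                dst[i] = (h < 0 || h >= H) ? 0.0 : src[h];
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of k_im2col: fold the unfolded gradient back onto the input grid.
// [[Rcpp::export]]
NumericVector k_col2im(NumericMatrix M, IntegerVector dims,
                       int kh, int kw, int stride, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int oh = out_dim(H, kh, stride, pad), ow = out_dim(W, kw, stride, pad);
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  NumericVector x((R_xlen_t)H * W * N * C);
  double* xp = x.begin();
  const double* mp = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const R_xlen_t q = dh + (R_xlen_t)kh * (dw + (R_xlen_t)kw * c);
        const double* col = mp + q * nrow;
        for (int n = 0; n < N; ++n) {
          double* xnc = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          for (int j = 0; j < ow; ++j) {
            const int w = j * stride + dw - pad;
            if (w < 0 || w >= W) continue;
            const double* src = col + (R_xlen_t)oh * (j + (R_xlen_t)ow * n);
            double* dst = xnc + (R_xlen_t)H * w;
            for (int i = 0; i < oh; ++i) {
              const int h = i * stride + dh - pad;
              if (h >= 0 && h < H) dst[h] += src[i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = dims;
  return x;
}

// Max pooling with argmax bookkeeping (0-based linear indices into x) so the
// backward pass is a scatter-add. Padded taps never win (treated as -Inf).
// [[Rcpp::export]]
List k_maxpool(NumericVector x, IntegerVector dims,
               int kh, int kw, int stride, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int oh = out_dim(H, kh, stride, pad), ow = out_dim(W, kw, stride, pad);
  const R_xlen_t nout = (R_xlen_t)oh * ow * N * C;
  NumericVector out(nout);
  NumericVector idx(nout);  // double to allow > 2^31 element inputs
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const R_xlen_t base = (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double best = -DBL_MAX; R_xlen_t bi = -1;
          for (int dw = 0; dw < kw; ++dw) {
            const int w = j * stride + dw - pad;
            if (w < 0 || w >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int h = i * stride + dh - pad;
              if (h < 0 || h >= H) continue;
              const R_xlen_t li = base + h + (R_xlen_t)H * w;
              if (xp[li] > best) { best = xp[li]; bi = li; }
            }
          }
          const R_xlen_t o = i + (R_xlen_t)oh * (j + (R_xlen_t)ow *
                             (n + (R_xlen_t)N * c));
          out[o] = best; idx[o] = (double)bi;
        }
    }
  out.attr("dim") = IntegerVector::create(oh, ow, N, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector k_maxpool_bwd(NumericVector gout, NumericVector idx,
                            IntegerVector dims) {
  NumericVector gx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  for (R_xlen_t o = 0; o < gout.size(); ++o) {
    const R_xlen_t li = (R_xlen_t)idx[o];
    if (li >= 0) gx[li] += gout[o];
  }
  gx.attr("dim") = dims;
  return gx;
}

static inline void lin_coef(int i, int in, int out, int& i0, int& i1,
                            double& w1) {
  // half-pixel-centre bilinear source coordinate (align_corners = FALSE)
  double s = ((double)i + 0.5) * in / out - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, in - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector k_bilinear(NumericVector x, IntegerVector dims,
                         int oh, int ow) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector out((R_xlen_t)oh * ow * N * C);
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<double> ah(oh), aw(ow);
  for (int i = 0; i < oh; ++i) lin_coef(i, H, oh, h0[i], h1[i], ah[i]);
  for (int j = 0; j < ow; ++j) lin_coef(j, W, ow, w0[j], w1[j], aw[j]);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    const double* xs = xp + (R_xlen_t)H * W * nc;
    double* os = op + (R_xlen_t)oh * ow * nc;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double a = ah[i], b = aw[j];
        const double v =
          (1 - a) * (1 - b) * xs[h0[i] + (R_xlen_t)H * w0[j]] +
          a       * (1 - b) * xs[h1[i] + (R_xlen_t)H * w0[j]] +
          (1 - a) * b       * xs[h0[i] + (R_xlen_t)H * w1[j]] +
          a       * b       * xs[h1[i] + (R_xlen_t)H * w1[j]];
        os[i + (R_xlen_t)oh * j] = v;
      }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, N, C);
  return out;
}

// [[Rcpp::export]]
NumericVector k_bilinear_bwd(NumericVector gout, IntegerVector dims,
                             int oh, int ow) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector gx((R_xlen_t)H * W * N * C);
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<double> ah(oh), aw(ow);
  for (int i = 0; i < oh; ++i) lin_coef(i, H, oh, h0[i], h1[i], ah[i]);
  for (int j = 0; j < ow; ++j) lin_coef(j, W, ow, w0[j], w1[j], aw[j]);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    double* xs = xp + (R_xlen_t)H * W * nc;
    const double* gs = gp + (R_xlen_t)oh * ow * nc;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double g = gs[i + (R_xlen_t)oh * j];
        const double a = ah[i], b = aw[j];
        xs[h0[i] + (R_xlen_t)H * w0[j]] += (1 - a) * (1 - b) * g;
        xs[h1[i] + (R_xlen_t)H * w0[j]] += a       * (1 - b) * g;
        xs[h0[i] + (R_xlen_t)H * w1[j]] += (1 - a) * b       * g;
        xs[h1[i] + (R_xlen_t)H * w1[j]] += a       * b       * g;
      }
  }
  gx.attr("dim") = dims;
  return gx;
}

// Adaptive average pooling to a bh x bw grid; window i covers rows
// [floor(i*H/bh), ceil((i+1)*H/bh)).
// [[Rcpp::export]]
NumericVector k_adaptive_avgpool(NumericVector x, IntegerVector dims,
                                 int bh, int bw) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector out((R_xlen_t)bh * bw * N * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    const double* xs = xp + (R_xlen_t)H * W * nc;
    double* os = op + (R_xlen_t)bh * bw * nc;
    for (int j = 0; j < bw; ++j) {
      const int w0 = (int)std::floor((double)j * W / bw);
      const int w1 = (int)std::ceil((double)(j + 1) * W / bw);
      for (int i = 0; i < bh; ++i) {
        const int h0 = (int)std::floor((double)i * H / bh);
        const int h1 = (int)std::ceil((double)(i + 1) * H / bh);
        double s = 0;
        for (int w = w0; w < w1; ++w)
          for (int h = h0; h < h1; ++h) s += xs[h + (R_xlen_t)H * w];
        os[i + (R_xlen_t)bh * j] = s / ((h1 - h0) * (w1 - w0));
      }
    }
  }
  out.attr("dim") = IntegerVector::create(bh, bw, N, C);
  return out;
}

// [[Rcpp::export]]
NumericVector k_adaptive_avgpool_bwd(NumericVector gout, IntegerVector dims,
                                     int bh, int bw) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector gx((R_xlen_t)H * W * N * C);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    double* xs = xp + (R_xlen_t)H * W * nc;
    const double* gs = gp + (R_xlen_t)bh * bw * nc;
    for (int j = 0; j < bw; ++j) {
      const int w0 = (int)std::floor((double)j * W / bw);
      const int w1 = (int)std::ceil((double)(j + 1) * W / bw);
      for (int i = 0; i < bh; ++i) {
        const int h0 = (int)std::floor((double)i * H / bh);
        const int h1 = (int)std::ceil((double)(i + 1) * H / bh);
        const double g = gs[i + (R_xlen_t)bh * j] / ((h1 - h0) * (w1 - w0));
        for (int w = w0; w < w1; ++w)
          for (int h = h0; h < h1; ++h) xs[h + (R_xlen_t)H * w] += g;
      }
    }
  }
  gx.attr("dim") = dims;
  return gx;
}

// Connected-component labelling of a binary H x W matrix. Labels are
// assigned in raster-scan order (row by row, left to right) of each
// component's first pixel, starting at 1.
// [[Rcpp::export]]
IntegerMatrix k_label_components(IntegerMatrix fg, int connectivity) {
  const int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* dx = connectivity == 8 ? dx8 : dx4;
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int nd = connectivity == 8 ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w) {
      if (!fg(h, w) || lab(h, w)) continue;
      lab(h, w) = ++next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        const int ch = q.front().first, cw = q.front().second; q.pop();
        for (int d = 0; d < nd; ++d) {
          const int nh = ch + dy[d], nw = cw + dx[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (fg(nh, nw) && !lab(nh, nw)) {
            lab(nh, nw) = next;
            q.push(std::make_pair(nh, nw));
          }
        }
      }
    }
  return lab;
}

// ---- fused elementwise kernels (hot paths of the training loop) -----------

// In-place Adam update; moments live in the parameter node.
// [[Rcpp::export]]
void k_adam(NumericVector p, NumericVector m, NumericVector v,
            NumericVector g, double lr, double b1, double b2,
            double eps, double c1, double c2) {
  const R_xlen_t n = p.size();
  double* pp = p.begin(); double* mp = m.begin();
  double* vp = v.begin(); const double* gp = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// In-place per-channel bias add; x has contiguous channel slabs of `slab`.
// [[Rcpp::export]]
void k_add_bias(NumericVector x, NumericVector b) {
  const R_xlen_t slab = x.size() / b.size();
  double* xp = x.begin();
  for (R_xlen_t c = 0; c < b.size(); ++c) {
    const double bc = b[c];
    for (R_xlen_t i = 0; i < slab; ++i) xp[c * slab + i] += bc;
  }
}

// Per-channel mean and biased variance of x viewed as (m x C).
// [[Rcpp::export]]
List k_bn_stats(NumericVector x, int C) {
  const R_xlen_t m = x.size() / C;
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    const double* xs = xp + (R_xlen_t)m * c;
    for (R_xlen_t i = 0; i < m; ++i) { s += xs[i]; }
    const double mean = s / m;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double d = xs[i] - mean; s2 += d * d;
    }
    mu[c] = mean; var[c] = s2 / m;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// out = (x - mu) * inv * gamma + beta, channelwise.
// [[Rcpp::export]]
NumericVector k_bn_apply(NumericVector x, NumericVector mu, NumericVector inv,
                         NumericVector gamma, NumericVector beta) {
  const int C = mu.size();
  const R_xlen_t m = x.size() / C;
  NumericVector out(x.size());
  const double* xp = x.begin(); double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double a = inv[c] * gamma[c];
    const double b = beta[c] - mu[c] * a;
    const double* xs = xp + m * c; double* os = op + m * c;
    for (R_xlen_t i = 0; i < m; ++i) os[i] = xs[i] * a + b;
  }
  return out;
}

// Batch-norm backward (training mode): returns gx, dgamma, dbeta.
// [[Rcpp::export]]
List k_bn_bwd(NumericVector x, NumericVector g, NumericVector mu,
              NumericVector inv, NumericVector gamma, bool training) {
  const int C = mu.size();
  const R_xlen_t m = x.size() / C;
  NumericVector gx(x.size()), dgamma(C), dbeta(C);
  const double* xp = x.begin(); const double* gp = g.begin();
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xs = xp + m * c; const double* gs = gp + m * c;
    double* os = op + m * c;
    double sg = 0, sgx = 0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double xh = (xs[i] - mu[c]) * inv[c];
      sg += gs[i];
      sgx += gs[i] * xh;
    }
    dgamma[c] = sgx; dbeta[c] = sg;
    const double a = gamma[c] * inv[c];
    if (training) {
      const double mg = sg / m, mgx = sgx / m;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double xh = (xs[i] - mu[c]) * inv[c];
        os[i] = a * (gs[i] - mg - xh * mgx);
      }
    } else {
      for (R_xlen_t i = 0; i < m; ++i) os[i] = a * gs[i];
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector k_relu(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin(); double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0;
  return out;
}

// [[Rcpp::export]]
NumericVector k_relu_bwd(NumericVector g, NumericVector out) {
  NumericVector gx(g.size());
  const double* gp = g.begin(); const double* op = out.begin();
  double* xp = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) xp[i] = op[i] > 0 ? gp[i] : 0;
  return gx;
}

// [[Rcpp::export]]
NumericVector k_sigmoid(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin(); double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector k_sigmoid_bwd(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  const double* gp = g.begin(); const double* yp = y.begin();
  double* xp = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) xp[i] = gp[i] * yp[i] * (1 - yp[i]);
  return gx;
}
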