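// Low-level dense compute kernels for the conv-net engine.
//
// Layout conventions (match R's column-major arrays):
//   2D feature maps: dim (H, W, C)
//   3D feature maps: dim (D, H, W, C)
//   conv weights:    matrix (prod(kernel) * C_in, C_out), kernel index fastest
// im2col is built transposed, (N_out x K), so row n enumerates output voxels
// in R array order and y = cols %*% W is laid out exactly as the R output
// array. Convolution arithmetic runs in single precision through chunked,
// exactly-filled im2col blocks: the host is memory-bandwidth-bound, so
// halving the bytes moved matters far more than the last float digits,
// which sit well below the optimizer's noise floor. Gradients are verified
// against finite differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static arma::fvec to_f(const double* x, size_t n) {
  arma::fvec v(n);
  for (size_t i = 0; i < n; ++i) v[i] = (float)x[i];
  return v;
}

// ---------------------------------------------------------------- 2D conv ---

// fill the transposed im2col block for output columns [w0, w1); every
// element is written exactly once (valid entries copied, the rest zeroed)
static void im2colT2d_chunk(const float* x, int H, int W, int C,
                            int KH, int KW, int s, int p, int Ho,
                            int w0, int w1, arma::fmat& cols) {
  int nw = w1 - w0;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = kh + KH * (kw + KW * c);
        float* colp = cols.colptr(r);
        for (int wi = 0; wi < nw; ++wi) {
          int w = (w0 + wi) * s - p + kw;
          float* dst = colp + (size_t)Ho * wi;
          if (w < 0 || w >= W) { std::memset(dst, 0, Ho * sizeof(float)); continue; }
          const float* xcol = x + (size_t)H * (w + (size_t)W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * s - p + kh;
            dst[ho] = (h >= 0 && h < H) ? xcol[h] : 0.0f;
          }
        }
      }
    }
  }
}

// chunk size (output columns per block) keeping the im2col block in cache
static int chunk_cols(size_t rows_per_col, size_t K, int total) {
  size_t target = 393216;   // ~1.5 MB of floats per block
  int nc = (int)std::max((size_t)1, target / (rows_per_col * K));
  return std::min(nc, total);
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, IntegerVector xdim,
                             NumericMatrix Wm, NumericVector b,
                             int KH, int KW, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Ho = out_len(H, KH, stride, pad), Wo = out_len(W, KW, stride, pad);
  int Co = Wm.ncol();
  size_t K = (size_t)KH * KW * C, N = (size_t)Ho * Wo;
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
    arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
  arma::fmat y(N, Co);
  int cw = chunk_cols(Ho, K, Wo);
  arma::fmat blk((size_t)Ho * cw, K);
  for (int w0 = 0; w0 < Wo; w0 += cw) {
    int w1 = std::min(Wo, w0 + cw);
    if (w1 - w0 < cw) blk.set_size((size_t)Ho * (w1 - w0), K);
    im2colT2d_chunk(xf.memptr(), H, W, C, KH, KW, stride, pad, Ho, w0, w1, blk);
    y.rows((size_t)Ho * w0, (size_t)Ho * w1 - 1) = blk * Wf;
  }
  NumericVector out(N * Co);
  for (int co = 0; co < Co; ++co) {
    double* op = out.begin() + N * co;
    const float* yp = y.colptr(co);
    double bc = b[co];
    for (size_t i = 0; i < N; ++i) op[i] = (double)yp[i] + bc;
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector gy, NumericVector x, IntegerVector xdim,
                     NumericMatrix Wm, int KH, int KW, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Ho = out_len(H, KH, stride, pad), Wo = out_len(W, KW, stride, pad);
  int Co = Wm.ncol();
  size_t N = (size_t)Ho * Wo, K = (size_t)KH * KW * C;
  arma::fvec gyf = to_f(gy.begin(), gy.size());
  arma::fmat Gy(gyf.memptr(), N, Co, false);
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
    arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
  arma::fmat gW(K, Co, arma::fill::zeros);
  arma::frowvec gbf = arma::sum(Gy, 0);
  arma::fvec gxf((size_t)H * W * C, arma::fill::zeros);
  float* gxp = gxf.memptr();
  int cw = chunk_cols(Ho, K, Wo);
  arma::fmat blk((size_t)Ho * cw, K);
  for (int w0 = 0; w0 < Wo; w0 += cw) {
    int w1 = std::min(Wo, w0 + cw);
    if (w1 - w0 < cw) blk.set_size((size_t)Ho * (w1 - w0), K);
    size_t r0 = (size_t)Ho * w0, r1 = (size_t)Ho * w1 - 1;
    im2colT2d_chunk(xf.memptr(), H, W, C, KH, KW, stride, pad, Ho, w0, w1, blk);
    gW += blk.t() * Gy.rows(r0, r1);
    arma::fmat gcols = Gy.rows(r0, r1) * Wf.t();   // (chunkN, K)
    int nw = w1 - w0;
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          int r = kh + KH * (kw + KW * c);
          const float* colp = gcols.colptr(r);
          for (int wi = 0; wi < nw; ++wi) {
            int w = (w0 + wi) * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            float* xcol = gxp + (size_t)H * (w + (size_t)W * c);
            const float* src = colp + (size_t)Ho * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              int h = ho * stride - pad + kh;
              if (h >= 0 && h < H) xcol[h] += src[ho];
            }
          }
        }
      }
    }
  }
  NumericVector gx(gxf.begin(), gxf.end());
  gx.attr("dim") = xdim;
  arma::mat gWd = arma::conv_to<arma::mat>::from(gW);
  return List::create(_["gx"] = gx, _["gW"] = wrap(gWd),
                      _["gb"] = NumericVector(gbf.begin(), gbf.end()));
}

// ---------------------------------------------------------------- 3D conv ---

static void im2colT3d_chunk(const float* x, int D, int H, int W, int C,
                            int K, int s, int p, int Do, int Ho,
                            int w0, int w1, arma::fmat& cols) {
  int nw = w1 - w0;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        for (int kd = 0; kd < K; ++kd) {
          int r = kd + K * (kh + K * (kw + K * c));
          float* colp = cols.colptr(r);
          for (int wi = 0; wi < nw; ++wi) {
            int w = (w0 + wi) * s - p + kw;
            if (w < 0 || w >= W) {
              std::memset(colp + (size_t)Do * Ho * wi, 0,
                          (size_t)Do * Ho * sizeof(float));
              continue;
            }
            for (int ho = 0; ho < Ho; ++ho) {
              int h = ho * s - p + kh;
              float* dst = colp + (size_t)Do * (ho + (size_t)Ho * wi);
              if (h < 0 || h >= H) {
                std::memset(dst, 0, Do * sizeof(float));
                continue;
              }
              const float* xrun =
                x + (size_t)D * (h + (size_t)H * (w + (size_t)W * c));
              if (s == 1) {
                int d0 = std::max(0, p - kd);            // first valid do
                int d1 = std::min(Do, D + p - kd);       // one past last
                for (int dd = 0; dd < d0; ++dd) dst[dd] = 0.0f;
                if (d1 > d0)
                  std::memcpy(dst + d0, xrun + d0 - p + kd,
                              (size_t)(d1 - d0) * sizeof(float));
                for (int dd = std::max(d0, d1); dd < Do; ++dd) dst[dd] = 0.0f;
              } else {
                for (int dd = 0; dd < Do; ++dd) {
                  int d = dd * s - p + kd;
                  dst[dd] = (d >= 0 && d < D) ? xrun[d] : 0.0f;
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector xdim,
                             NumericMatrix Wm, NumericVector b,
                             int K, int stride, int pad) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int Do = out_len(D, K, stride, pad), Ho = out_len(H, K, stride, pad),
      Wo = out_len(W, K, stride, pad);
  int Co = Wm.ncol();
  size_t Kc = (size_t)K * K * K * C, N = (size_t)Do * Ho * Wo;
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
    arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
  arma::fmat y(N, Co);
  int cw = chunk_cols((size_t)Do * Ho, Kc, Wo);
  arma::fmat blk((size_t)Do * Ho * cw, Kc);
  for (int w0 = 0; w0 < Wo; w0 += cw) {
    int w1 = std::min(Wo, w0 + cw);
    if (w1 - w0 < cw) blk.set_size((size_t)Do * Ho * (w1 - w0), Kc);
    im2colT3d_chunk(xf.memptr(), D, H, W, C, K, stride, pad, Do, Ho,
                    w0, w1, blk);
    y.rows((size_t)Do * Ho * w0, (size_t)Do * Ho * w1 - 1) = blk * Wf;
  }
  NumericVector out(N * Co);
  for (int co = 0; co < Co; ++co) {
    double* op = out.begin() + N * co;
    const float* yp = y.colptr(co);
    double bc = b[co];
    for (size_t i = 0; i < N; ++i) op[i] = (double)yp[i] + bc;
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector gy, NumericVector x, IntegerVector xdim,
                     NumericMatrix Wm, int K, int stride, int pad) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int Do = out_len(D, K, stride, pad), Ho = out_len(H, K, stride, pad),
      Wo = out_len(W, K, stride, pad);
  int Co = Wm.ncol();
  size_t N = (size_t)Do * Ho * Wo, Kc = (size_t)K * K * K * C;
  arma::fvec gyf = to_f(gy.begin(), gy.size());
  arma::fmat Gy(gyf.memptr(), N, Co, false);
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
    arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
  arma::fmat gW(Kc, Co, arma::fill::zeros);
  arma::frowvec gbf = arma::sum(Gy, 0);
  arma::fvec gxf((size_t)D * H * W * C, arma::fill::zeros);
  float* gxp = gxf.memptr();
  int cw = chunk_cols((size_t)Do * Ho, Kc, Wo);
  arma::fmat blk((size_t)Do * Ho * cw, Kc);
  for (int w0 = 0; w0 < Wo; w0 += cw) {
    int w1 = std::min(Wo, w0 + cw);
    if (w1 - w0 < cw) blk.set_size((size_t)Do * Ho * (w1 - w0), Kc);
    size_t r0 = (size_t)Do * Ho * w0, r1 = (size_t)Do * Ho * w1 - 1;
    im2colT3d_chunk(xf.memptr(), D, H, W, C, K, stride, pad, Do, Ho,
                    w0, w1, blk);
    gW += blk.t() * Gy.rows(r0, r1);
    arma::fmat gcols = Gy.rows(r0, r1) * Wf.t();
    int nw = w1 - w0;
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < K; ++kw) {
        for (int kh = 0; kh < K; ++kh) {
          for (int kd = 0; kd < K; ++kd) {
            int r = kd + K * (kh + K * (kw + K * c));
            const float* colp = gcols.colptr(r);
            for (int wi = 0; wi < nw; ++wi) {
              int w = (w0 + wi) * stride - pad + kw;
              if (w < 0 || w >= W) continue;
              for (int ho = 0; ho < Ho; ++ho) {
                int h = ho * stride - pad + kh;
                if (h < 0 || h >= H) continue;
                float* xrun =
                  gxp + (size_t)D * (h + (size_t)H * (w + (size_t)W * c));
                const float* src =
                  colp + (size_t)Do * (ho + (size_t)Ho * wi);
                if (stride == 1) {
                  int d0 = std::max(0, pad - kd);
                  int d1 = std::min(Do, D + pad - kd);
                  float* xs = xrun - pad + kd;
                  for (int dd = d0; dd < d1; ++dd) xs[dd] += src[dd];
                } else {
                  for (int dd = 0; dd < Do; ++dd) {
                    int d = dd * stride - pad + kd;
                    if (d >= 0 && d < D) xrun[d] += src[dd];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  NumericVector gx(gxf.begin(), gxf.end());
  gx.attr("dim") = xdim;
  arma::mat gWd = arma::conv_to<arma::mat>::from(gW);
  return List::create(_["gx"] = gx, _["gW"] = wrap(gWd),
                      _["gb"] = NumericVector(gbf.begin(), gbf.end()));
}

// ------------------------------------------------------------- pooling -----

// 2x2x2 max pooling, stride 2; dims must be even.
// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x, IntegerVector xdim) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  size_t N = (size_t)Do * Ho * Wo * C;
  NumericVector y(N);
  IntegerVector arg(N);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int dd = 0; dd < Do; ++dd) {
          double best = -INFINITY; size_t besti = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                size_t i = (2 * dd + kd) +
                  (size_t)D * ((2 * ho + kh) +
                  (size_t)H * ((2 * wo + kw) + (size_t)W * c));
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          size_t o = dd + (size_t)Do * (ho + (size_t)Ho * (wo + (size_t)Wo * c));
          y[o] = best; arg[o] = (int)besti;
        }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward(NumericVector gy, IntegerVector arg,
                                 IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[arg[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// --------------------------------------------------------- upsampling ------

// nearest-neighbour 2x upsampling along the first `nd` spatial dims
// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x, IntegerVector xdim, int nd) {
  if (nd == 2) {
    int H = xdim[0], W = xdim[1], C = xdim[2];
    NumericVector y((size_t)4 * H * W * C);
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < 2 * W; ++w)
        for (int h = 0; h < 2 * H; ++h)
          y[h + (size_t)2 * H * (w + (size_t)2 * W * c)] =
            x[h / 2 + (size_t)H * (w / 2 + (size_t)W * c)];
    y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
    return y;
  }
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  NumericVector y((size_t)8 * D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < 2 * W; ++w)
      for (int h = 0; h < 2 * H; ++h)
        for (int d = 0; d < 2 * D; ++d)
          y[d + (size_t)2 * D * (h + (size_t)2 * H * (w + (size_t)2 * W * c))] =
            x[d / 2 + (size_t)D * (h / 2 + (size_t)H * (w / 2 + (size_t)W * c))];
  y.attr("dim") = IntegerVector::create(2 * D, 2 * H, 2 * W, C);
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector gy, IntegerVector xdim, int nd) {
  if (nd == 2) {
    int H = xdim[0], W = xdim[1], C = xdim[2];
    NumericVector gx((size_t)H * W * C);
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < 2 * W; ++w)
        for (int h = 0; h < 2 * H; ++h)
          gx[h / 2 + (size_t)H * (w / 2 + (size_t)W * c)] +=
            gy[h + (size_t)2 * H * (w + (size_t)2 * W * c)];
    gx.attr("dim") = xdim;
    return gx;
  }
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  NumericVector gx((size_t)D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < 2 * W; ++w)
      for (int h = 0; h < 2 * H; ++h)
        for (int d = 0; d < 2 * D; ++d)
          gx[d / 2 + (size_t)D * (h / 2 + (size_t)H * (w / 2 + (size_t)W * c))] +=
            gy[d + (size_t)2 * D * (h + (size_t)2 * H * (w + (size_t)2 * W * c))];
  gx.attr("dim") = xdim;
  return gx;
}

// ------------------------------------------------- 2D affine resampling ----

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  return p1 + 0.5 * t * (p2 - p0 +
           t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
           t * (3.0 * (p1 - p2) + p3 - p0)));
}

// Inverse-map each output pixel through a 2x2 linear map about the image
// centre: src = A %*% (dst - centre) + centre. interp: 0 nearest, 1 bicubic
// (Catmull-Rom); borders handled by reflection.
// [[Rcpp::export(name = ".warp_affine2d")]]
NumericMatrix warp_affine2d(NumericMatrix img, NumericMatrix A, int interp) {
  int H = img.nrow(), W = img.ncol();
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double dy = i - cy, dx = j - cx;
      double sy = A(0, 0) * dy + A(0, 1) * dx + cy;
      double sx = A(1, 0) * dy + A(1, 1) * dx + cx;
      if (interp == 0) {
        int yi = reflect_idx((int)std::lround(sy), H);
        int xi = reflect_idx((int)std::lround(sx), W);
        out(i, j) = img(yi, xi);
      } else {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double ty = sy - y0, tx = sx - x0;
        double col[4];
        for (int m = -1; m <= 2; ++m) {
          double row[4];
          for (int k = -1; k <= 2; ++k)
            row[k + 1] = img(reflect_idx(y0 + k, H), reflect_idx(x0 + m, W));
          col[m + 1] = catmull_rom(row[0], row[1], row[2], row[3], ty);
        }
        out(i, j) = catmull_rom(col[0], col[1], col[2], col[3], tx);
      }
    }
  }
  return out;
}
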