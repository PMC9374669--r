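#include <Rcpp.h>
using namespace Rcpp;

// Tensor memory layout used throughout: R arrays, column-major.
//   batch   x: dim (H, W, C, N)   -> x[h + H*(w + W*(c + C*n))]
//   kernels w: dim (kh, kw, C, Nk) flattened to a (kh*kw*C) x Nk matrix
// "same_ceil" padding offsets (pad_top, pad_left) are computed on the R side.

static inline int out_size(int in, int stride) { return (in + stride - 1) / stride; }

// Unfold x into a (Hout*Wout*N) x (kh*kw*C) matrix for a GEMM-based conv.
// Row order is (ho, wo, n); column order matches the column-major flattening
// of a (kh, kw, C) kernel block.
// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad_top, int pad_left) {
  const int Hout = out_size(H, stride), Wout = out_size(W, stride);
  const R_xlen_t nrow = (R_xlen_t)Hout * Wout * N;
  NumericMatrix M(nrow, kh * kw * C);
  const double *px = x.begin();
  double *pm = M.begin();
  for (int ch = 0; ch < C; ++ch) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const R_xlen_t col = (R_xlen_t)(i + kh * (j + kw * ch)) * nrow;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t xoff = (R_xlen_t)H * W * (ch + (R_xlen_t)C * n);
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride + j - pad_left;
            const R_xlen_t rbase = col + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
            if (wi < 0 || wi >= W) continue; // zero padding (M starts zeroed)
            const R_xlen_t xcol = xoff + (R_xlen_t)H * wi;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride + i - pad_top;
              if (hi < 0 || hi >= H) continue;
              pm[rbase + ho] = px[xcol + hi];
            }
          }
        }
      }
    }
  }
  return M;
}

// Fold a gradient matrix (same shape as the im2col output) back onto the
// input tensor, accumulating where patches overlapped.
// [[Rcpp::export(name = ".cpp_col2im")]]
NumericVector cpp_col2im(NumericMatrix G, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad_top, int pad_left) {
  const int Hout = out_size(H, stride), Wout = out_size(W, stride);
  const R_xlen_t nrow = (R_xlen_t)Hout * Wout * N;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pg = G.begin();
  double *px = gx.begin();
  for (int ch = 0; ch < C; ++ch) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const R_xlen_t col = (R_xlen_t)(i + kh * (j + kw * ch)) * nrow;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t xoff = (R_xlen_t)H * W * (ch + (R_xlen_t)C * n);
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride + j - pad_left;
            if (wi < 0 || wi >= W) continue;
            const R_xlen_t rbase = col + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
            const R_xlen_t xcol = xoff + (R_xlen_t)H * wi;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride + i - pad_top;
              if (hi < 0 || hi >= H) continue;
              px[xcol + hi] += pg[rbase + ho];
            }
          }
        }
      }
    }
  }
  return gx;
}

// Depthwise conv: one kh x kw filter per input channel, w dim (kh, kw, C).
// [[Rcpp::export(name = ".cpp_dwconv_fwd")]]
NumericVector cpp_dwconv_fwd(NumericVector x, int H, int W, int C, int N,
                             NumericVector w, int kh, int kw, int stride,
                             int pad_top, int pad_left) {
  const int Hout = out_size(H, stride), Wout = out_size(W, stride);
  NumericVector y((R_xlen_t)Hout * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      const R_xlen_t xoff = (R_xlen_t)H * W * (ch + (R_xlen_t)C * n);
      const R_xlen_t yoff = (R_xlen_t)Hout * Wout * (ch + (R_xlen_t)C * n);
      const double *wc = pw + (R_xlen_t)kh * kw * ch;
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          double acc = 0.0;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * stride + j - pad_left;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * stride + i - pad_top;
              if (hi < 0 || hi >= H) continue;
              acc += px[xoff + hi + (R_xlen_t)H * wi] * wc[i + kh * j];
            }
          }
          py[yoff + ho + (R_xlen_t)Hout * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd")]]
List cpp_dwconv_bwd(NumericVector x, int H, int W, int C, int N,
                    NumericVector w, int kh, int kw, int stride,
                    int pad_top, int pad_left, NumericVector gy) {
  const int Hout = out_size(H, stride), Wout = out_size(W, stride);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((R_xlen_t)kh * kw * C);
  gw.attr("dim") = IntegerVector::create(kh, kw, C);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      const R_xlen_t xoff = (R_xlen_t)H * W * (ch + (R_xlen_t)C * n);
      const R_xlen_t yoff = (R_xlen_t)Hout * Wout * (ch + (R_xlen_t)C * n);
      const double *wc = pw + (R_xlen_t)kh * kw * ch;
      double *gwc = pgw + (R_xlen_t)kh * kw * ch;
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          const double g = pg[yoff + ho + (R_xlen_t)Hout * wo];
          if (g == 0.0) continue;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * stride + j - pad_left;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * stride + i - pad_top;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t xi = xoff + hi + (R_xlen_t)H * wi;
              gwc[i + kh * j] += g * px[xi];
              pgx[xi] += g * wc[i + kh * j];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Bilinear affine warp of a single (H, W, C) image. `inv` is the 2x3 matrix
// of the OUTPUT->INPUT map in (x, y) = (col, row) coordinates with 0-based
// pixel centers: xi = a*xo + b*yo + tx ; yi = c*xo + d*yo + ty.
// Out-of-bounds samples take `fill`.
// [[Rcpp::export(name = ".cpp_warp_affine")]]
NumericVector cpp_warp_affine(NumericVector img, int H, int W, int C,
                              NumericVector inv, int Hout, int Wout, double fill) {
  NumericVector out((R_xlen_t)Hout * Wout * C);
  out.attr("dim") = IntegerVector::create(Hout, Wout, C);
  const double a = inv[0], b = inv[1], tx = inv[2];
  const double c = inv[3], d = inv[4], ty = inv[5];
  const double *pi = img.begin();
  double *po = out.begin();
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const double xi = a * wo + b * ho + tx;
      const double yi = c * wo + d * ho + ty;
      const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      const double fx = xi - x0, fy = yi - y0;
      for (int ch = 0; ch < C; ++ch) {
        const R_xlen_t off = (R_xlen_t)H * W * ch;
        double v = 0.0;
        for (int dy = 0; dy <= 1; ++dy) {
          for (int dx = 0; dx <= 1; ++dx) {
            const int xx = x0 + dx, yy = y0 + dy;
            const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
            const double s = (xx < 0 || xx >= W || yy < 0 || yy >= H)
                                 ? fill
                                 : pi[off + yy + (R_xlen_t)H * xx];
            v += wgt * s;
          }
        }
        po[(R_xlen_t)Hout * Wout * ch + ho + (R_xlen_t)Hout * wo] = v;
      }
    }
  }
  return out;
}

// Fused batch-norm affine + activation: y = act(x * a[c] + b[c]).
// act codes: 0 linear, 1 relu, 2 relu6.
// [[Rcpp::export(name = ".cpp_bnact_fwd")]]
NumericVector cpp_bnact_fwd(NumericVector x, int HW, int C, int N,
                            NumericVector a, NumericVector b, int act) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *px = x.begin(), *pa = a.begin(), *pb = b.begin();
  double *py = y.begin();
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = pa[c], bc = pb[c];
      for (int k = 0; k < HW; ++k, ++i) {
        double z = px[i] * ac + bc;
        if (act >= 1 && z < 0) z = 0;
        if (act == 2 && z > 6) z = 6;
        py[i] = z;
      }
    }
  }
  return y;
}

// Backward of the fused op: gz = gy * act'(z), z recomputed from x, a, b.
// [[Rcpp::export(name = ".cpp_bnact_bwd")]]
NumericVector cpp_bnact_bwd(NumericVector x, int HW, int C, int N,
                            NumericVector a, NumericVector b,
                            NumericVector gy, int act) {
  NumericVector gz(x.size());
  gz.attr("dim") = x.attr("dim");
  const double *px = x.begin(), *pa = a.begin(), *pb = b.begin(),
               *pg = gy.begin();
  double *po = gz.begin();
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = pa[c], bc = pb[c];
      for (int k = 0; k < HW; ++k, ++i) {
        const double z = px[i] * ac + bc;
        bool pass = true;
        if (act >= 1 && z <= 0) pass = false;
        if (act == 2 && z >= 6) pass = false;
        po[i] = pass ? pg[i] : 0.0;
      }
    }
  }
  return gz;
}

// Per-channel mean and (biased) variance over (H*W, N).
// [[Rcpp::export(name = ".cpp_channel_stats")]]
List cpp_channel_stats(NumericVector x, int HW, int C, int N) {
  NumericVector mu(C), var(C);
  const double *px = x.begin();
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int k = 0; k < HW; ++k, ++i) {
        s += px[i];
        s2 += px[i] * px[i];
      }
      mu[c] += s;
      var[c] += s2;
    }
  }
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= M;
    var[c] = var[c] / M - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// Fused training-mode BN backward given gz (gradient at the BN output):
//   gx = gamma*invstd * (gz - (gbeta + xhat*ggamma)/M),  xhat=(x-mu)*invstd
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector x, int HW, int C, int N, NumericVector mu,
                NumericVector invstd, NumericVector gamma, NumericVector gz,
                bool training) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  const double *px = x.begin(), *pg = gz.begin();
  const double M = (double)HW * N;
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double sg = 0, sgx = 0;
      for (int k = 0; k < HW; ++k, ++i) {
        sg += pg[i];
        sgx += pg[i] * (px[i] - mu[c]) * invstd[c];
      }
      gbeta[c] += sg;
      ggamma[c] += sgx;
    }
  }
  i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double aic = gamma[c] * invstd[c];
      for (int k = 0; k < HW; ++k, ++i) {
        if (training) {
          const double xhat = (px[i] - mu[c]) * invstd[c];
          gx[i] = aic * (pg[i] - (gbeta[c] + xhat * ggamma[c]) / M);
        } else {
          gx[i] = aic * pg[i];
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
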