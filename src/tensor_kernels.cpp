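// Convolution kernels for the segmentation network.
//
// Tensor layout convention throughout: feature maps are R arrays of
// dim c(H, W, C, N) (column-major, H fastest). Conv weights are
// dim c(kh, kw, Cin, Cout); depthwise weights c(kh, kw, C).
// Dense convolutions go through im2col + GEMM so they hit BLAS.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v(R_xlen_t((size_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill col (K x P) for one sample. K = kh*kw*Ci (dh fastest, then dw, then ci),
// P = OH*OW (oh fastest). x points at the sample's (H,W,Ci) block.
static void im2col(const double* x, int H, int W, int Ci,
                   int kh, int kw, int stride, int pad,
                   arma::mat& col) {
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int p = oh + OH * ow;
      double* cp = col.colptr(p);
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = x + (size_t)ci * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          const int iw = ow * stride - pad + dw;
          for (int dh = 0; dh < kh; ++dh) {
            const int ih = oh * stride - pad + dh;
            const int k = dh + kh * (dw + kw * ci);
            cp[k] = (ih >= 0 && ih < H && iw >= 0 && iw < W)
                      ? xc[ih + (size_t)H * iw] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add col (K x P) back into the sample's gradient block.
static void col2im(const arma::mat& col, int H, int W, int Ci,
                   int kh, int kw, int stride, int pad, double* dx) {
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int p = oh + OH * ow;
      const double* cp = col.colptr(p);
      for (int ci = 0; ci < Ci; ++ci) {
        double* xc = dx + (size_t)ci * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          const int iw = ow * stride - pad + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int ih = oh * stride - pad + dh;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (size_t)H * iw] += cp[dh + kh * (dw + kw * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("conv2d: input has %d channels, weight expects %d", Ci, wd[2]);
  const int OH = out_dim(H, kh, stride, pad), OW = out_dim(W, kw, stride, pad);
  const int K = kh * kw * Ci, P = OH * OW;
  NumericVector out = alloc4(OH, OW, Co, N);
  arma::mat Wmat(w.begin(), K, Co, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Ci, H, W, Ci, kh, kw, stride, pad, col);
    arma::mat Y(out.begin() + (size_t)n * P * Co, P, Co, false, true);
    Y = col.t() * Wmat;
    for (int co = 0; co < Co; ++co) Y.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int OH = out_dim(H, kh, stride, pad), OW = out_dim(W, kw, stride, pad);
  const int K = kh * kw * Ci, P = OH * OW;
  NumericVector dx = alloc4(H, W, Ci, N);
  NumericVector dw = alloc4(kh, kw, Ci, Co);
  NumericVector db(Co);
  arma::mat Wmat(w.begin(), K, Co, false, true);
  arma::mat dWmat(dw.begin(), K, Co, false, true);
  arma::vec dbv(db.begin(), Co, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Ci, H, W, Ci, kh, kw, stride, pad, col);
    arma::mat dY(dy.begin() + (size_t)n * P * Co, P, Co, false, true);
    dWmat += col * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dcol = Wmat * dY.t();  // K x P
    col2im(dcol, H, W, Ci, kh, kw, stride, pad, dx.begin() + (size_t)n * H * W * Ci);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise convolution, stride 1. w dims c(kh, kw, C).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_dwconv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                              int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv2d: input has %d channels, weight expects %d", C, wd[2]);
  NumericVector out = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      double* yc = out.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double bc = b[c];
      for (int ow = 0; ow < W; ++ow) {
        for (int oh = 0; oh < H; ++oh) {
          double acc = bc;
          for (int dw2 = 0; dw2 < kw; ++dw2) {
            const int iw = ow - pad + dw2;
            if (iw < 0 || iw >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int ih = oh - pad + dh;
              if (ih < 0 || ih >= H) continue;
              acc += xc[ih + (size_t)H * iw] * wc[dh + kh * dw2];
            }
          }
          yc[oh + (size_t)H * ow] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_dwconv2d_bw(NumericVector x, NumericVector w, NumericVector dy, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw(Dimension(kh, kw, C));
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* dyc = dy.begin() + (size_t)(c + (size_t)n * C) * H * W;
      double* dxc = dx.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      double* dwc = dw.begin() + (size_t)c * kh * kw;
      double dbacc = 0.0;
      for (int ow = 0; ow < W; ++ow) {
        for (int oh = 0; oh < H; ++oh) {
          const double g = dyc[oh + (size_t)H * ow];
          dbacc += g;
          for (int dw2 = 0; dw2 < kw; ++dw2) {
            const int iw = ow - pad + dw2;
            if (iw < 0 || iw >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int ih = oh - pad + dh;
              if (ih < 0 || ih >= H) continue;
              dxc[ih + (size_t)H * iw] += g * wc[dh + kh * dw2];
              dwc[dh + kh * dw2] += g * xc[ih + (size_t)H * iw];
            }
          }
        }
      }
      db[c] += dbacc;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 transposed convolution (the decoder's upsampler).
// w dims c(2, 2, Ci, Co); output is (2H, 2W, Co, N); no overlap at this
// kernel/stride so each output pixel has exactly one contributing input.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_convtr2x2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  if (wd[2] != Ci) stop("convtr2x2: input has %d channels, weight expects %d", Ci, wd[2]);
  const int OH = 2 * H, OW = 2 * W;
  const size_t P = (size_t)H * W;
  NumericVector out = alloc4(OH, OW, Co, N);
  arma::mat Wab(Ci, Co);
  for (int a = 0; a < 2; ++a) {
    for (int bb = 0; bb < 2; ++bb) {
      for (int co = 0; co < Co; ++co)
        for (int ci = 0; ci < Ci; ++ci)
          Wab(ci, co) = w[a + 2 * (bb + 2 * (ci + (size_t)Ci * co))];
      for (int n = 0; n < N; ++n) {
        arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * P * Ci, P, Ci, false, true);
        arma::mat Y = X * Wab;  // P x Co
        for (int co = 0; co < Co; ++co) {
          double* oc = out.begin() + ((size_t)co + (size_t)n * Co) * OH * OW;
          const double* yc = Y.colptr(co);
          const double bc = b[co];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              oc[(2 * i + a) + (size_t)OH * (2 * j + bb)] = yc[i + (size_t)H * j] + bc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_convtr2x2_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int OH = 2 * H, OW = 2 * W;
  const size_t P = (size_t)H * W;
  NumericVector dx = alloc4(H, W, Ci, N);
  NumericVector dw = alloc4(2, 2, Ci, Co);
  NumericVector db(Co);
  arma::mat Wab(Ci, Co), dYab(P, Co);
  for (int a = 0; a < 2; ++a) {
    for (int bb = 0; bb < 2; ++bb) {
      for (int co = 0; co < Co; ++co)
        for (int ci = 0; ci < Ci; ++ci)
          Wab(ci, co) = w[a + 2 * (bb + 2 * (ci + (size_t)Ci * co))];
      arma::mat dWab(Ci, Co, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        for (int co = 0; co < Co; ++co) {
          const double* dyc = dy.begin() + ((size_t)co + (size_t)n * Co) * OH * OW;
          double* dp = dYab.colptr(co);
          double dbacc = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = dyc[(2 * i + a) + (size_t)OH * (2 * j + bb)];
              dp[i + (size_t)H * j] = g;
              dbacc += g;
            }
          db[co] += dbacc;
        }
        arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * P * Ci, P, Ci, false, true);
        arma::mat dX(dx.begin() + (size_t)n * P * Ci, P, Ci, false, true);
        dX += dYab * Wab.t();
        dWab += X.t() * dYab;
      }
      for (int co = 0; co < Co; ++co)
        for (int ci = 0; ci < Ci; ++ci)
          dw[a + 2 * (bb + 2 * (ci + (size_t)Ci * co))] = dWab(ci, co);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Channels-first layer normalization: normalize over the channel axis at
// each spatial position (ConvNext convention). gamma/beta length C.
// [[Rcpp::export(rng = false)]]
List cpp_layernorm_cf_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                         double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  NumericVector xhat = alloc4(H, W, C, N);
  NumericVector invstd = alloc4(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    double* yn = y.begin() + (size_t)n * HW * C;
    double* xh = xhat.begin() + (size_t)n * HW * C;
    double* isd = invstd.begin() + (size_t)n * HW;
    for (size_t p = 0; p < HW; ++p) {
      double mu = 0.0, var = 0.0;
      for (int c = 0; c < C; ++c) mu += xn[p + HW * c];
      mu /= C;
      for (int c = 0; c < C; ++c) {
        const double d = xn[p + HW * c] - mu;
        var += d * d;
      }
      var /= C;
      const double is = 1.0 / std::sqrt(var + eps);
      isd[p] = is;
      for (int c = 0; c < C; ++c) {
        const double xv = (xn[p + HW * c] - mu) * is;
        xh[p + HW * c] = xv;
        yn[p + HW * c] = gamma[c] * xv + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export(rng = false)]]
List cpp_layernorm_cf_bw(NumericVector dy, NumericVector xhat, NumericVector invstd,
                         NumericVector gamma) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * HW * C;
    const double* xh = xhat.begin() + (size_t)n * HW * C;
    const double* isd = invstd.begin() + (size_t)n * HW;
    double* dxn = dx.begin() + (size_t)n * HW * C;
    for (size_t p = 0; p < HW; ++p) {
      double m1 = 0.0, m2 = 0.0;
      for (int c = 0; c < C; ++c) {
        const double dxh = dyn[p + HW * c] * gamma[c];
        m1 += dxh;
        m2 += dxh * xh[p + HW * c];
      }
      m1 /= C; m2 /= C;
      for (int c = 0; c < C; ++c) {
        const double dxh = dyn[p + HW * c] * gamma[c];
        dxn[p + HW * c] = isd[p] * (dxh - m1 - xh[p + HW * c] * m2);
        dgamma[c] += dyn[p + HW * c] * xh[p + HW * c];
        dbeta[c] += dyn[p + HW * c];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
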