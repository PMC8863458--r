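// Low-level network kernels.
//
// Activation layout: a batch of C-channel feature maps of spatial size H x W
// is a numeric array with dim (H*W, B, C); spatial index s = h + H*w
// (column-major within a map).  With this layout one channel of the whole
// batch is a contiguous block of H*W*B doubles, which keeps the batch-norm
// reductions cache-friendly, and the im2col GEMM output can be copied
// straight into the destination array.
//
// Convolution weights: array (kh, kw, Cin, Cout) flattened column-major to a
// (kh*kw*Cin) x Cout matrix, i.e. row r = dh + kh*(dw + kw*c).
//
// Convolutions use "same" zero padding (odd kernel extents enforced on the R
// side).  GEMMs run in single precision: feature values and gradients in a
// network of this size are nowhere near double-precision scale limits, and
// sgemm roughly doubles memory throughput.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the im2col matrix for the whole batch.
// cols is (kh*kw*Cin) x (H*W*B); column j = s + HW*b holds the receptive
// field of output position s in sample b.
static void im2col_fill(const double* x, arma::fmat& cols,
                        int H, int W, int B, int Cin, int kh, int kw) {
  const int HW = H * W, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int b = 0; b < B; ++b) {
    for (int w0 = 0; w0 < W; ++w0) {
      for (int h0 = 0; h0 < H; ++h0) {
        float* cp = cols.colptr((size_t)HW * b + h0 + (size_t)H * w0);
        int r = 0;
        for (int c = 0; c < Cin; ++c) {
          const double* xc = x + (size_t)HW * (b + (size_t)B * c);
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = w0 + dw - pw;
            if (wi < 0 || wi >= W) {
              for (int dh = 0; dh < kh; ++dh) cp[r++] = 0.0f;
              continue;
            }
            const double* xcol = xc + (size_t)H * wi;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h0 + dh - ph;
              cp[r++] = (hi < 0 || hi >= H) ? 0.0f : (float)xcol[hi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of the im2col-shaped gradient back onto the input grid.
static void col2im_acc(const arma::fmat& dcols, double* dx,
                       int H, int W, int B, int Cin, int kh, int kw) {
  const int HW = H * W, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int b = 0; b < B; ++b) {
    for (int w0 = 0; w0 < W; ++w0) {
      for (int h0 = 0; h0 < H; ++h0) {
        const float* cp = dcols.colptr((size_t)HW * b + h0 + (size_t)H * w0);
        int r = 0;
        for (int c = 0; c < Cin; ++c) {
          double* xc = dx + (size_t)HW * (b + (size_t)B * c);
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = w0 + dw - pw;
            if (wi < 0 || wi >= W) { r += kh; continue; }
            double* xcol = xc + (size_t)H * wi;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h0 + dh - ph;
              if (hi >= 0 && hi < H) xcol[hi] += (double)cp[r];
              ++r;
            }
          }
        }
      }
    }
  }
}

// Standard convolution, forward.  Returns the output array and (optionally)
// an external pointer to the im2col matrix so the backward pass can reuse it.
// [[Rcpp::export]]
List nn_conv_fw(NumericVector x, int H, int W, int B, int Cin,
                NumericMatrix wmat, int kh, int kw, bool keep_cache) {
  const int HW = H * W, K = kh * kw * Cin, Cout = wmat.ncol();
  if (wmat.nrow() != K) stop("weight matrix rows != kh*kw*Cin");
  arma::fmat* cols = new arma::fmat(K, (size_t)HW * B);
  im2col_fill(x.begin(), *cols, H, W, B, Cin, kh, kw);
  arma::fmat Wf(K, Cout);
  std::copy(wmat.begin(), wmat.end(), Wf.begin());
  arma::fmat Y = cols->t() * Wf;  // (HW*B) x Cout
  NumericVector y((size_t)HW * B * Cout);
  std::copy(Y.begin(), Y.end(), y.begin());
  y.attr("dim") = IntegerVector::create(HW, B, Cout);
  List out = List::create(_["y"] = y);
  if (keep_cache) {
    out["cache"] = XPtr<arma::fmat>(cols, true);
  } else {
    delete cols;
  }
  return out;
}

// Standard convolution, backward.  `cache` is the XPtr produced by the
// forward pass.  Returns dW (always) and dx (only if want_dx).
// [[Rcpp::export]]
List nn_conv_bw(SEXP cache, NumericVector dy, int H, int W, int B, int Cin,
                NumericMatrix wmat, int kh, int kw, bool want_dx) {
  const int HW = H * W, K = kh * kw * Cin, Cout = wmat.ncol();
  XPtr<arma::fmat> cols(cache);
  arma::fmat dY((size_t)HW * B, Cout);
  std::copy(dy.begin(), dy.end(), dY.begin());
  arma::fmat dWf = (*cols) * dY;  // K x Cout
  NumericMatrix dW(K, Cout);
  std::copy(dWf.begin(), dWf.end(), dW.begin());
  List out = List::create(_["dW"] = dW);
  if (want_dx) {
    arma::fmat Wf(K, Cout);
    std::copy(wmat.begin(), wmat.end(), Wf.begin());
    arma::fmat dcols = Wf * dY.t();  // K x (HW*B)
    NumericVector dx((size_t)HW * B * Cin);  // zero-initialised
    col2im_acc(dcols, dx.begin(), H, W, B, Cin, kh, kw);
    dx.attr("dim") = IntegerVector::create(HW, B, Cin);
    out["dx"] = dx;
  }
  return out;
}

// Depthwise convolution: one (kh x kw) kernel per channel, channel i of the
// output depends only on channel i of the input.  wd is (kh*kw) x C.
// [[Rcpp::export]]
NumericVector nn_dwconv_fw(NumericVector x, int H, int W, int B, int C,
                           NumericMatrix wd, int kh, int kw) {
  const int HW = H * W, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((size_t)HW * B * C);
  for (int c = 0; c < C; ++c) {
    const double* wk = &wd(0, c);
    for (int b = 0; b < B; ++b) {
      const double* xc = x.begin() + (size_t)HW * (b + (size_t)B * c);
      double* yc = y.begin() + (size_t)HW * (b + (size_t)B * c);
      for (int w0 = 0; w0 < W; ++w0) {
        for (int h0 = 0; h0 < H; ++h0) {
          double acc = 0.0;
          int r = 0;
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = w0 + dw - pw;
            if (wi < 0 || wi >= W) { r += kh; continue; }
            const double* xcol = xc + (size_t)H * wi;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h0 + dh - ph;
              if (hi >= 0 && hi < H) acc += wk[r] * xcol[hi];
              ++r;
            }
          }
          yc[h0 + (size_t)H * w0] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(HW, B, C);
  return y;
}

// [[Rcpp::export]]
List nn_dwconv_bw(NumericVector x, NumericVector dy, int H, int W, int B,
                  int C, NumericMatrix wd, int kh, int kw) {
  const int HW = H * W, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericMatrix dWd(kh * kw, C);
  NumericVector dx((size_t)HW * B * C);
  for (int c = 0; c < C; ++c) {
    const double* wk = &wd(0, c);
    double* dwk = &dWd(0, c);
    for (int b = 0; b < B; ++b) {
      const double* xc = x.begin() + (size_t)HW * (b + (size_t)B * c);
      const double* gyc = dy.begin() + (size_t)HW * (b + (size_t)B * c);
      double* gxc = dx.begin() + (size_t)HW * (b + (size_t)B * c);
      for (int w0 = 0; w0 < W; ++w0) {
        for (int h0 = 0; h0 < H; ++h0) {
          const double g = gyc[h0 + (size_t)H * w0];
          if (g == 0.0) continue;
          int r = 0;
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = w0 + dw - pw;
            if (wi < 0 || wi >= W) { r += kh; continue; }
            const double* xcol = xc + (size_t)H * wi;
            double* gxcol = gxc + (size_t)H * wi;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h0 + dh - ph;
              if (hi >= 0 && hi < H) {
                dwk[r] += g * xcol[hi];
                gxcol[hi] += g * wk[r];
              }
              ++r;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(HW, B, C);
  return List::create(_["dW"] = dWd, _["dx"] = dx);
}

// Non-overlapping max pooling with window (ph, pw) == stride; trailing rows
// or columns that do not fill a window are dropped.
// [[Rcpp::export]]
List nn_maxpool_fw(NumericVector x, int H, int W, int B, int C,
                   int ph, int pw) {
  const int HW = H * W, H2 = H / ph, W2 = W / pw, HW2 = H2 * W2;
  NumericVector y((size_t)HW2 * B * C);
  IntegerVector idx((size_t)HW2 * B * C);  // winning input spatial index
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* xc = x.begin() + (size_t)HW * (b + (size_t)B * c);
      double* yc = y.begin() + (size_t)HW2 * (b + (size_t)B * c);
      int* ic = idx.begin() + (size_t)HW2 * (b + (size_t)B * c);
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          double best = -HUGE_VAL;
          int besti = -1;
          for (int dw = 0; dw < pw; ++dw) {
            for (int dh = 0; dh < ph; ++dh) {
              const int s = (h2 * ph + dh) + (size_t)H * (w2 * pw + dw);
              if (xc[s] > best) { best = xc[s]; besti = s; }
            }
          }
          yc[h2 + (size_t)H2 * w2] = best;
          ic[h2 + (size_t)H2 * w2] = besti;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(HW2, B, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bw(NumericVector dy, IntegerVector idx, int H, int W,
                            int B, int C, int H2, int W2) {
  const int HW = H * W, HW2 = H2 * W2;
  NumericVector dx((size_t)HW * B * C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* gyc = dy.begin() + (size_t)HW2 * (b + (size_t)B * c);
      const int* ic = idx.begin() + (size_t)HW2 * (b + (size_t)B * c);
      double* gxc = dx.begin() + (size_t)HW * (b + (size_t)B * c);
      for (int s = 0; s < HW2; ++s) gxc[ic[s]] += gyc[s];
    }
  }
  dx.attr("dim") = IntegerVector::create(HW, B, C);
  return dx;
}

// Fused batch normalisation + ReLU, forward.  x is treated as (N, C) with
// N = H*W*B (one contiguous block per channel).  In training mode the batch
// mean and biased variance are computed here and returned; in inference mode
// the supplied running statistics are used.
// [[Rcpp::export]]
List nn_bn_relu_fw(NumericVector x, double n_elem, int C,
                   NumericVector gamma, NumericVector beta,
                   NumericVector mean_in, NumericVector var_in,
                   bool use_given, double eps) {
  const size_t N = (size_t)n_elem;
  NumericVector y(N * C), mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    double m, v;
    if (use_given) {
      m = mean_in[c]; v = var_in[c];
    } else {
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < N; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m = s / N;
      v = s2 / N - m * m;
      if (v < 0) v = 0;  // numerical guard
    }
    mu[c] = m; var[c] = v;
    const double scale = gamma[c] / std::sqrt(v + eps);
    const double shift = beta[c] - m * scale;
    double* yc = y.begin() + N * c;
    for (size_t i = 0; i < N; ++i) {
      const double t = xc[i] * scale + shift;
      yc[i] = t > 0 ? t : 0.0;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// Fused ReLU + batch-norm backward (training mode, batch statistics).
// y is the forward output (used for the ReLU mask).
// [[Rcpp::export]]
List nn_bn_relu_bw(NumericVector x, NumericVector y, NumericVector dy,
                   double n_elem, int C, NumericVector gamma,
                   NumericVector mu, NumericVector var, double eps) {
  const size_t N = (size_t)n_elem;
  NumericVector dx(N * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    const double* yc = y.begin() + N * c;
    const double* gyc = dy.begin() + N * c;
    double* gxc = dx.begin() + N * c;
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double m = mu[c];
    double sg = 0.0, sb = 0.0;
    for (size_t i = 0; i < N; ++i) {
      const double g = yc[i] > 0 ? gyc[i] : 0.0;
      sb += g;
      sg += g * (xc[i] - m) * istd;
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double k = gamma[c] * istd;
    for (size_t i = 0; i < N; ++i) {
      const double g = yc[i] > 0 ? gyc[i] : 0.0;
      const double xhat = (xc[i] - m) * istd;
      gxc[i] = k * (g - sb / N - xhat * sg / N);
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
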