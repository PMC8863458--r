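// Fused branch kernels: the whole five-stage branch network runs forward
// and backward in single C++ calls, in single precision, with every
// intermediate held in a persistent workspace keyed by a caller-supplied
// tag.  This avoids per-step allocation and double<->float conversion
// between stages; kernels.cpp keeps the simple one-op-per-call reference
// implementations these are tested against.
//
// Layouts.  Activations are sample-major float blocks: sample b of a
// C-channel map of H*W positions occupies the (HW x C) block at columns
// [b*C, (b+1)*C) of a workspace matrix, spatial index s = h + H*w inside a
// column.  Convolution weights keep the R-side contract: (kh*kw*Cin) x Cout
// with row r = dh + kh*(dw + kw*c).  "Same" zero padding, odd kernels.
//
// The im2col of the (single-channel) first-layer input never changes during
// training, so it is computed once per fold into a cached "set": sample j's
// (HW x K) block sits at columns [j*K, (j+1)*K), and each per-sample
// convolution is one NT GEMM against it.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-precision GEMM from the linked BLAS, called directly so products
// land in the persistent workspace blocks without temporaries.
extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb,
            const float* beta, float* c, const int* ldc);
}
static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

static std::map<std::string, arma::fmat>& ws_f() {
  static std::map<std::string, arma::fmat> m;
  return m;
}
static std::map<std::string, std::vector<unsigned char> >& ws_i() {
  static std::map<std::string, std::vector<unsigned char> > m;
  return m;
}
static arma::fmat& ws_get(const std::string& tag, size_t n_rows,
                          size_t n_cols) {
  arma::fmat& b = ws_f()[tag];
  if (b.n_rows != n_rows || b.n_cols != n_cols) b.set_size(n_rows, n_cols);
  return b;
}
static std::vector<unsigned char>& ws_get_i(const std::string& tag,
                                             size_t n) {
  std::vector<unsigned char>& b = ws_i()[tag];
  if (b.size() != n) b.resize(n);
  return b;
}

// [[Rcpp::export]]
void nn_ws_clear() { ws_f().clear(); ws_i().clear(); }

// ---------------------------------------------------------------------------
// cached im2col set
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void nn_im2col_set(List xs, int H, int W, int kh, int kw,
                   std::string set_tag) {
  const int HW = H * W, K = kh * kw, n = xs.size();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::fmat& set = ws_get(set_tag, HW, (size_t)K * n);
  for (int j = 0; j < n; ++j) {
    NumericVector x(xs[j]);
    const double* xp = x.begin();
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        float* cp = set.colptr((size_t)K * j + dh + kh * dw);
        for (int w0 = 0; w0 < W; ++w0) {
          const int wi = w0 + dw - pw;
          float* cc = cp + (size_t)H * w0;
          if (wi < 0 || wi >= W) {
            std::fill(cc, cc + H, 0.0f);
            continue;
          }
          const double* xcol = xp + (size_t)H * wi + (dh - ph);
          const int h_lo = std::max(0, ph - dh);
          const int h_hi = std::min(H, H + ph - dh);
          for (int h0 = 0; h0 < h_lo; ++h0) cc[h0] = 0.0f;
          for (int h0 = h_lo; h0 < h_hi; ++h0) cc[h0] = (float)xcol[h0];
          for (int h0 = h_hi; h0 < H; ++h0) cc[h0] = 0.0f;
        }
      }
    }
  }
}

// Zero-copy alias of sample j's (HW x K) im2col block.
static arma::fmat cols_view(arma::fmat& set, size_t HW, int K, int j) {
  return arma::fmat(set.colptr((size_t)K * j), HW, K, false, true);
}
// Zero-copy alias of sample b's (HW x C) activation block.
static arma::fmat smp_view(arma::fmat& a, size_t HW, int C, int b) {
  return arma::fmat(a.colptr((size_t)C * b), HW, C, false, true);
}
static inline size_t blk(int b, int c, int C, size_t HW) {
  return HW * ((size_t)c + (size_t)C * b);  // sample-major
}

// ---------------------------------------------------------------------------
// stage pieces (all sample-major float)
// ---------------------------------------------------------------------------

static void bn_stats(const arma::fmat& z, size_t HW, int B, int C,
                     double* mu, double* var) {
  const size_t N = HW * B;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int b = 0; b < B; ++b) {
      const float* zc = z.memptr() + blk(b, c, C, HW);
      for (size_t i = 0; i < HW; ++i) {
        s += zc[i]; s2 += (double)zc[i] * zc[i];
      }
    }
    const double m = s / N;
    double v = s2 / N - m * m;
    mu[c] = m;
    var[c] = v < 0 ? 0 : v;
  }
}

// Batch norm + ReLU + max pool, evaluated on the fly from the convolution
// output z; records each winner's input spatial index for the backward
// pass.  A (ph, pw) of (1, 1) degenerates to plain batch norm + ReLU.
// The winner of each pool window is recorded as a byte code dh + ph*dw;
// the backward pass reconstructs the spatial index from the window
// coordinates, keeping the index array 4x smaller than the activation.
static void bn_relu_pool(const arma::fmat& z, float* y, unsigned char* idx,
                         int H, int W, int B, int C, int ph, int pw,
                         const double* gamma, const double* beta,
                         const double* mu, const double* var, double eps) {
  const size_t HW = (size_t)H * W;
  const int H2 = H / ph, W2 = W / pw;
  const size_t HW2 = (size_t)H2 * W2;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double scale = gamma[c] / std::sqrt(var[c] + eps);
      const double shift = beta[c] - mu[c] * scale;
      const float* zc = z.memptr() + blk(b, c, C, HW);
      float* yc = y + HW2 * ((size_t)c + (size_t)C * b);
      unsigned char* ic = idx + HW2 * ((size_t)c + (size_t)C * b);
      if (ph == 1 && pw == 1) {
        for (size_t s = 0; s < HW; ++s) {
          const double t = zc[s] * scale + shift;
          yc[s] = t > 0 ? (float)t : 0.0f;
          ic[s] = 0;
        }
        continue;
      }
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          double best = -HUGE_VAL;
          int bestc = 0;
          for (int dw = 0; dw < pw; ++dw) {
            for (int dh = 0; dh < ph; ++dh) {
              const int s = (h2 * ph + dh) + H * (w2 * pw + dw);
              const double t = zc[s] * scale + shift;
              if (t > best) { best = t; bestc = dh + ph * dw; }
            }
          }
          yc[h2 + (size_t)H2 * w2] = best > 0 ? (float)best : 0.0f;
          ic[h2 + (size_t)H2 * w2] = (unsigned char)bestc;
        }
      }
    }
  }
}

// Backward of the bn+relu+pool tail: scatter the pooled gradient dy onto
// the conv output grid through the winner indices and the ReLU mask, then
// apply the batch-norm chain rule (training statistics), producing the
// dense dz and the dgamma/dbeta reductions.
static void tail_bw(const arma::fmat& z, arma::fmat& dz, const float* dy,
                    const std::vector<unsigned char>& idx, int H, int W,
                    int B, int C, int ph, int pw, const double* gamma,
                    const double* beta, const double* mu, const double* var,
                    double eps, double* dgamma, double* dbeta) {
  const size_t HW = (size_t)H * W;
  const int H2 = H / ph, W2 = W / pw;
  const size_t HW2 = (size_t)H2 * W2;
  const size_t N = HW * B;
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double m = mu[c];
    const double scale = gamma[c] * istd;
    const double shift = beta[c] - m * scale;
    double sg = 0.0, sb = 0.0;
    for (int b = 0; b < B; ++b) {
      float* dzc = dz.memptr() + blk(b, c, C, HW);
      std::fill(dzc, dzc + HW, 0.0f);
      const float* zc = z.memptr() + blk(b, c, C, HW);
      const float* gyc = dy + HW2 * ((size_t)c + (size_t)C * b);
      const unsigned char* ic = idx.data() + HW2 * ((size_t)c +
                                                    (size_t)C * b);
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          const size_t s2 = h2 + (size_t)H2 * w2;
          const double g = gyc[s2];
          if (g == 0.0) continue;
          const int code = ic[s2];
          const int s = (h2 * ph + code % ph) + H * (w2 * pw + code / ph);
          const double zv = zc[s];
          if (zv * scale + shift <= 0) continue;  // ReLU mask
          dzc[s] += (float)g;
          sb += g;
          sg += g * (zv - m) * istd;
        }
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double t1 = sb / N, t2 = sg / N;
    for (int b = 0; b < B; ++b) {
      const float* zc = z.memptr() + blk(b, c, C, HW);
      float* dzc = dz.memptr() + blk(b, c, C, HW);
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (zc[i] - m) * istd;
        dzc[i] = (float)(scale * (dzc[i] - t1 - xhat * t2));
      }
    }
  }
}

// Depthwise convolution, tap-by-tap over contiguous runs.
static void dwconv_fw(const arma::fmat& x, arma::fmat& zd, int H, int W,
                      int B, int C, const double* wd, int kh, int kw) {
  const size_t HW = (size_t)H * W;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  zd.zeros();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* wk = wd + (size_t)kh * kw * c;
      const float* xc = x.memptr() + blk(b, c, C, HW);
      float* zc = zd.memptr() + blk(b, c, C, HW);
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const float wv = (float)wk[dh + kh * dw];
          if (wv == 0.0f) continue;
          for (int w0 = 0; w0 < W; ++w0) {
            const int wi = w0 + dw - pw;
            if (wi < 0 || wi >= W) continue;
            const int h_lo = std::max(0, ph - dh);
            const int h_hi = std::min(H, H + ph - dh);
            const float* xcol = xc + (size_t)H * wi + (dh - ph);
            float* zcol = zc + (size_t)H * w0;
            for (int h0 = h_lo; h0 < h_hi; ++h0) zcol[h0] += wv * xcol[h0];
          }
        }
      }
    }
  }
}

static void dwconv_bw(const arma::fmat& x, const arma::fmat& dzd,
                      arma::fmat* dx, int H, int W, int B, int C,
                      const double* wd, int kh, int kw, double* dwd) {
  const size_t HW = (size_t)H * W;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  if (dx) dx->zeros();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* wk = wd + (size_t)kh * kw * c;
      double* dwk = dwd + (size_t)kh * kw * c;
      const float* xc = x.memptr() + blk(b, c, C, HW);
      const float* gc = dzd.memptr() + blk(b, c, C, HW);
      float* dxc = dx ? dx->memptr() + blk(b, c, C, HW) : nullptr;
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const float wv = (float)wk[dh + kh * dw];
          double acc = 0.0;
          for (int w0 = 0; w0 < W; ++w0) {
            const int wi = w0 + dw - pw;
            if (wi < 0 || wi >= W) continue;
            const int h_lo = std::max(0, ph - dh);
            const int h_hi = std::min(H, H + ph - dh);
            const float* xcol = xc + (size_t)H * wi + (dh - ph);
            const float* gcol = gc + (size_t)H * w0;
            if (dxc) {
              float* dxcol = dxc + (size_t)H * wi + (dh - ph);
              for (int h0 = h_lo; h0 < h_hi; ++h0) {
                acc += (double)xcol[h0] * gcol[h0];
                dxcol[h0] += wv * gcol[h0];
              }
            } else {
              for (int h0 = h_lo; h0 < h_hi; ++h0) {
                acc += (double)xcol[h0] * gcol[h0];
              }
            }
          }
          dwk[dh + kh * dw] += acc;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// whole-branch forward / backward
// ---------------------------------------------------------------------------

struct StageDesc {
  int kind;            // 0 = standard conv (stage 1), 1 = depthwise separable
  int kh, kw, cin, cout, ph, pw;
  int H, W;            // input spatial dims
};

// spec: one row per stage: kind, kh, kw, cin, cout, ph, pw
// (ph = pw = 1 means no pooling after the stage)
static std::vector<StageDesc> parse_spec(const IntegerMatrix& spec,
                                         int H, int W) {
  std::vector<StageDesc> out;
  for (int i = 0; i < spec.nrow(); ++i) {
    StageDesc st{spec(i, 0), spec(i, 1), spec(i, 2), spec(i, 3),
                 spec(i, 4), spec(i, 5), spec(i, 6), H, W};
    out.push_back(st);
    H /= st.ph; W /= st.pw;
  }
  return out;
}

static std::string stag(const std::string& tag, int i, const char* what) {
  return tag + "." + std::to_string(i) + what;
}

// Forward through the whole branch.  `params`/`state` are the R-side
// per-stage parameter and running-statistics lists.  Returns the (B x Cout)
// feature matrix produced by global average pooling plus each stage's batch
// statistics; in training mode the float intermediates stay cached under
// `tag` for nn_branch_bw.
// [[Rcpp::export]]
List nn_branch_fw(std::string set_tag, IntegerVector sel,
                  IntegerMatrix spec, List params, List state,
                  double eps, bool training, int H, int W,
                  std::string tag) {
  const int B = sel.size();
  std::vector<StageDesc> stages = parse_spec(spec, H, W);
  arma::fmat& set = ws_f()[set_tag];
  List means(stages.size()), vars(stages.size());
  arma::fmat* a_prev = nullptr;
  for (size_t i = 0; i < stages.size(); ++i) {
    const StageDesc& st = stages[i];
    const size_t HW = (size_t)st.H * st.W;
    List p = params[i];
    List s = state[i];
    NumericVector gamma = p["g"], beta = p["b"];
    arma::fmat* z = &ws_get(stag(tag, i, ".z"), HW, (size_t)B * st.cout);
    if (st.kind == 0) {
      NumericVector wv = p["W"];
      const int K = st.kh * st.kw * st.cin;
      const arma::mat wm(wv.begin(), K, st.cout, false, true);
      arma::fmat Wf = arma::conv_to<arma::fmat>::from(wm);
      for (int b = 0; b < B; ++b) {
        sgemm('N', 'N', HW, st.cout, K, 1.0f,
              set.colptr((size_t)K * (sel[b] - 1)), HW, Wf.memptr(), K,
              0.0f, z->colptr((size_t)st.cout * b), HW);
      }
    } else {
      NumericMatrix wd = p["Wd"], wp = p["Wp"];
      arma::fmat& zd = ws_get(stag(tag, i, ".zd"), HW, (size_t)B * st.cin);
      dwconv_fw(*a_prev, zd, st.H, st.W, B, st.cin, wd.begin(), st.kh,
                st.kw);
      const arma::mat wpm(wp.begin(), st.cin, st.cout, false, true);
      arma::fmat Wpf = arma::conv_to<arma::fmat>::from(wpm);
      for (int b = 0; b < B; ++b) {
        sgemm('N', 'N', HW, st.cout, st.cin, 1.0f,
              zd.colptr((size_t)st.cin * b), HW, Wpf.memptr(), st.cin,
              0.0f, z->colptr((size_t)st.cout * b), HW);
      }
    }
    NumericVector mu(st.cout), var(st.cout);
    if (training) {
      bn_stats(*z, HW, B, st.cout, mu.begin(), var.begin());
    } else {
      NumericVector rm = s["rm"], rv = s["rv"];
      std::copy(rm.begin(), rm.end(), mu.begin());
      std::copy(rv.begin(), rv.end(), var.begin());
    }
    means[i] = mu; vars[i] = var;
    const size_t HW2 = HW / ((size_t)st.ph * st.pw);
    arma::fmat& a = ws_get(stag(tag, i, ".a"), HW2, (size_t)B * st.cout);
    std::vector<unsigned char>& idx =
      ws_get_i(stag(tag, i, ".idx"), HW2 * B * st.cout);
    bn_relu_pool(*z, a.memptr(), idx.data(), st.H, st.W, B, st.cout,
                 st.ph, st.pw, gamma.begin(), beta.begin(), mu.begin(),
                 var.begin(), eps);
    a_prev = &a;
  }
  // global average pooling over the final map
  const StageDesc& last = stages.back();
  const int C5 = last.cout;
  const size_t HWL = ((size_t)last.H / last.ph) * (last.W / last.pw);
  NumericMatrix feat(B, C5);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C5; ++c) {
      const float* ac = a_prev->memptr() + blk(b, c, C5, HWL);
      double sum = 0.0;
      for (size_t i = 0; i < HWL; ++i) sum += ac[i];
      feat(b, c) = sum / HWL;
    }
  }
  return List::create(_["feat"] = feat, _["means"] = means,
                      _["vars"] = vars);
}

// Backward through the whole branch from the feature gradient (B x Cout).
// Requires the forward pass to have run in training mode under the same
// tag.  Returns the per-stage parameter gradients; no input gradient is
// produced (the first layer consumes the data).
// [[Rcpp::export]]
List nn_branch_bw(std::string set_tag, IntegerVector sel,
                  IntegerMatrix spec, List params, List means, List vars,
                  NumericMatrix dfeat, double eps, int H, int W,
                  std::string tag) {
  const int B = sel.size();
  std::vector<StageDesc> stages = parse_spec(spec, H, W);
  arma::fmat& set = ws_f()[set_tag];
  const int n_stages = stages.size();
  List grads(n_stages);
  // seed the activation-gradient chain from the GAP backward
  const StageDesc& last = stages.back();
  const int C5 = last.cout;
  const size_t HWL = ((size_t)last.H / last.ph) * (last.W / last.pw);
  arma::fmat* da = &ws_get(stag(tag, n_stages - 1, ".dax"), HWL,
                           (size_t)B * C5);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C5; ++c) {
      float* dc = da->memptr() + blk(b, c, C5, HWL);
      std::fill(dc, dc + HWL, (float)(dfeat(b, c) / HWL));
    }
  }
  for (int i = n_stages - 1; i >= 0; --i) {
    const StageDesc& st = stages[i];
    const size_t HW = (size_t)st.H * st.W;
    List p = params[i];
    NumericVector gamma = p["g"], beta = p["b"];
    NumericVector mu = means[i], var = vars[i];
    arma::fmat& z = ws_f()[stag(tag, i, ".z")];
    std::vector<unsigned char>& idx = ws_i()[stag(tag, i, ".idx")];
    NumericVector dgamma(st.cout), dbeta(st.cout);
    if (st.kind == 0) {
      NumericVector wv = p["W"];
      const int K = st.kh * st.kw * st.cin;
      arma::fmat& dz1 = ws_get(stag(tag, i, ".dz"), HW,
                               (size_t)B * st.cout);
      tail_bw(z, dz1, da->memptr(), idx, st.H, st.W, B, st.cout, st.ph,
              st.pw, gamma.begin(), beta.begin(), mu.begin(), var.begin(),
              eps, dgamma.begin(), dbeta.begin());
      arma::fmat dWf(K, st.cout, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        sgemm('T', 'N', K, st.cout, HW, 1.0f,
              set.colptr((size_t)K * (sel[b] - 1)), HW,
              dz1.colptr((size_t)st.cout * b), HW, 1.0f, dWf.memptr(), K);
      }
      NumericVector dW(no_init(wv.size()));
      dW.attr("dim") = wv.attr("dim");
      std::copy(dWf.begin(), dWf.end(), dW.begin());
      grads[i] = List::create(_["W"] = dW, _["g"] = dgamma,
                              _["b"] = dbeta);
      continue;
    }
    arma::fmat& dz = ws_get(stag(tag, i, ".dz"), HW, (size_t)B * st.cout);
    tail_bw(z, dz, da->memptr(), idx, st.H, st.W, B, st.cout, st.ph,
            st.pw, gamma.begin(), beta.begin(), mu.begin(), var.begin(),
            eps, dgamma.begin(), dbeta.begin());
    {
      NumericMatrix wd = p["Wd"], wp = p["Wp"];
      const arma::mat wpm(wp.begin(), st.cin, st.cout, false, true);
      arma::fmat Wpf = arma::conv_to<arma::fmat>::from(wpm);
      arma::fmat& zd = ws_f()[stag(tag, i, ".zd")];
      arma::fmat dWp_f(st.cin, st.cout, arma::fill::zeros);
      arma::fmat& dzd = ws_get(stag(tag, i, ".dzd"), HW,
                               (size_t)B * st.cin);
      for (int b = 0; b < B; ++b) {
        const float* dzb = dz.colptr((size_t)st.cout * b);
        sgemm('T', 'N', st.cin, st.cout, HW, 1.0f,
              zd.colptr((size_t)st.cin * b), HW, dzb, HW, 1.0f,
              dWp_f.memptr(), st.cin);
        sgemm('N', 'T', HW, st.cin, st.cout, 1.0f, dzb, HW, Wpf.memptr(),
              st.cin, 0.0f, dzd.colptr((size_t)st.cin * b), HW);
      }
      NumericMatrix dWd(st.kh * st.kw, st.cin);
      arma::fmat& a_in = ws_f()[stag(tag, i - 1, ".a")];
      arma::fmat* dx = nullptr;
      if (i > 0) {
        dx = &ws_get(stag(tag, i - 1, ".dax"), HW, (size_t)B * st.cin);
      }
      dwconv_bw(a_in, dzd, dx, st.H, st.W, B, st.cin, wd.begin(), st.kh,
                st.kw, dWd.begin());
      NumericMatrix dWp(st.cin, st.cout);
      std::copy(dWp_f.begin(), dWp_f.end(), dWp.begin());
      grads[i] = List::create(_["Wd"] = dWd, _["Wp"] = dWp,
                              _["g"] = dgamma, _["b"] = dbeta);
      da = dx;
    }
  }
  return grads;
}
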