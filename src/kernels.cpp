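// Numerical kernels for the ROI-detection and diameter-tracking networks.
// All randomness (init, shuffling, dropout masks, augmentation) lives on the
// R side; these routines are deterministic functions of their arguments.
//
// The ROI detector's wide (kernel ~401) single-input-channel convolution is
// computed as per-depth dot products against a zero-margin-padded frame
// (both operands contiguous, cache resident). The tracker's narrow
// (kernel 9) multi-channel convolutions use a guard-row batch layout: a
// batch of B windows of length `len` with `ch` channels is one
// (B * lenp) x ch float matrix, lenp = len + 2*half, with `half` zero guard
// rows around each sample, so a zero-padded same-width convolution is a sum
// over kernel taps of offset GEMMs. Guard rows are re-zeroed after every
// layer, so full-column sums equal sums over valid rows, which batch
// normalization relies on. Row-chunking keeps the activations cache
// resident across the 9 tap GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// raw BLAS wrappers (blas_shim.cpp)
void lt_sgemm(char ta, char tb, int m, int n, int k, float alpha,
              const float* A, int lda, const float* B, int ldb, float beta,
              float* C, int ldc);
float lt_sdot(int n, const float* x, const float* y);

static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc) {
  lt_sgemm(ta, tb, m, n, k, alpha, A, lda, B, ldb, beta, C, ldc);
}

static inline float sdot(int n, const float* x, const float* y) {
  return lt_sdot(n, x, y);
}

// AVX-512 conv microkernels (conv_avx512.cpp), used when the CPU supports
// them; the BLAS tap path below is the portable fallback.
bool lt_conv_fwd_avx(const float* A, int ldA, const float* Wk, int k,
                     int ci, int co, const float* bias, float* Z, int ldZ,
                     int R);
bool lt_conv_dw_avx(const float* A, int ldA, const float* dZt, int k,
                    int ci, int co, float* dWk, int R);
void lt_transpose_avx(const float* Z, int ldZ, int R, int co, float* Zt);

static bool use_avx512() {
#if defined(__x86_64__) && defined(__GNUC__)
  static const bool ok = __builtin_cpu_supports("avx512f") != 0;
  return ok;
#else
  return false;
#endif
}

// depth-axis "same" convolution (zero-padded) of every column of X with a
// single odd-length kernel w. Used for the phantom Gabor pulse and the
// parameterless average-pooling layer.
// [[Rcpp::export]]
arma::mat cpp_conv1d_same(const arma::mat& X, const arma::vec& w) {
  const uword n = X.n_rows, B = X.n_cols;
  mat out(n, B);
  for (uword j = 0; j < B; ++j)
    out.col(j) = conv(X.col(j), w, "same");
  return out;
}

#if defined(__GNUC__) && !defined(__clang__) && defined(__x86_64__)
# define LT_MULTIVER \
  __attribute__((target_clones("arch=x86-64-v4", "arch=x86-64-v3", "default")))
#else
# define LT_MULTIVER
#endif

LT_MULTIVER
static void adam_kernel(double* __restrict p, double* __restrict m,
                        double* __restrict v, const double* __restrict g,
                        const R_xlen_t n, const double lr, const double wd,
                        const double b1, const double b2, const double eps,
                        const double c1, const double c2) {
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + wd * p[i];
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// Adam update, in place on the R arrays (p, m, v share memory with R).
// [[Rcpp::export]]
void cpp_adam_inplace(Rcpp::NumericVector p, Rcpp::NumericVector m,
                      Rcpp::NumericVector v, const Rcpp::NumericVector g,
                      const double lr, const double wd, const double b1,
                      const double b2, const double eps, const int t) {
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  adam_kernel(p.begin(), m.begin(), v.begin(), g.begin(), p.size(), lr, wd,
              b1, b2, eps, c1, c2);
}

// ---------------------------------------------------------------------------
// ROI detector: conv(1 -> C, kernel k, same) + ReLU, 1-wide conv(C -> 1),
// then parameterless moving-average pooling. Loss (training) is the MSE
// between the PRE-pooling map and the response vector.
// ---------------------------------------------------------------------------

// H (len x C) = relu(conv(frame) + b1) from the margin-padded frame xp
static void roi_conv_fwd(const float* xp, const int len, const float* W1,
                         const int k, const int C, const float* b1,
                         float* H) {
  for (int c = 0; c < C; ++c) {
    const float* w = W1 + c * k;
    float* h = H + c * len;
    const float bias = b1[c];
    for (int r = 0; r < len; ++r) {
      const float z = sdot(k, xp + r, w) + bias;
      h[r] = z > 0.0f ? z : 0.0f;
    }
  }
}

// dW1[t + c*k] += sum_r xp[r + t] * dH[r + c*len]
static void roi_conv_dw(const float* xp, const int len, const float* dH,
                        const int k, const int C, float* dW1) {
  for (int c = 0; c < C; ++c) {
    const float* dh = dH + c * len;
    float* w = dW1 + c * k;
    for (int t = 0; t < k; ++t) w[t] += sdot(len, xp + t, dh);
  }
}

// moving-average pooling with double accumulation (zero-padded, same length)
static void box_pool(const double* x, const int n, const int w, double* y) {
  const int h = w / 2;
  double s = 0.0;
  for (int i = 0; i < h && i < n; ++i) s += x[i];
  for (int i = 0; i < n; ++i) {
    if (i + h < n) s += x[i + h];
    if (i - h - 1 >= 0) s -= x[i - h - 1];
    y[i] = s / w;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_roi_forward(const arma::mat& X, const arma::mat& W1,
                           const arma::vec& b1, const arma::vec& w2,
                           const double b2, const int pool) {
  const int len = X.n_rows, B = X.n_cols, k = W1.n_rows, C = W1.n_cols;
  const int half = k / 2;
  const fmat W1f = conv_to<fmat>::from(W1);
  const fvec b1f = conv_to<fvec>::from(b1);
  const fvec w2f = conv_to<fvec>::from(w2);
  mat pre(len, B), pooled(len, B);
  fvec xp(len + 2 * half, fill::zeros);
  fmat H(len, C);
  for (int s = 0; s < B; ++s) {
    for (int i = 0; i < len; ++i) xp(half + i) = float(X(i, s));
    roi_conv_fwd(xp.memptr(), len, W1f.memptr(), k, C, b1f.memptr(),
                 H.memptr());
    for (int r = 0; r < len; ++r) {
      float acc = float(b2);
      for (int c = 0; c < C; ++c) acc += H(r, c) * w2f(c);
      pre(r, s) = double(acc);
    }
    box_pool(pre.colptr(s), len, pool, pooled.colptr(s));
  }
  return Rcpp::List::create(Rcpp::Named("pre") = pre,
                            Rcpp::Named("pooled") = pooled);
}

// Training step over a batch of frames. `shifts` applies the depth
// translation augmentation on the fly: frame s and its response vector are
// both translated by shifts[s] samples (zero fill), which is exactly the
// label-equivariant augmentation.
// [[Rcpp::export]]
Rcpp::List cpp_roi_grad(const arma::mat& X, const arma::mat& R,
                        const arma::mat& W1, const arma::vec& b1,
                        const arma::vec& w2, const double b2,
                        const arma::ivec& shifts) {
  const int len = X.n_rows, B = X.n_cols, k = W1.n_rows, C = W1.n_cols;
  const int half = k / 2;
  const fmat W1f = conv_to<fmat>::from(W1);
  const fvec b1f = conv_to<fvec>::from(b1);
  const fvec w2f = conv_to<fvec>::from(w2);
  const float scale = 1.0f / float(len * B);

  fmat dW1(k, C, fill::zeros);
  fvec db1(C, fill::zeros), dw2(C, fill::zeros);
  double db2 = 0.0, loss = 0.0;
  fvec xp(len + 2 * half);
  fmat H(len, C), dH(len, C);
  fvec dpre(len);

  for (int s = 0; s < B; ++s) {
    const int sh = (shifts.n_elem == uword(B)) ? int(shifts(s)) : 0;
    xp.zeros();
    {
      const int lo = std::max(0, sh), hi = std::min(len, len + sh);
      for (int i = lo; i < hi; ++i) xp(half + i) = float(X(i - sh, s));
    }
    roi_conv_fwd(xp.memptr(), len, W1f.memptr(), k, C, b1f.memptr(),
                 H.memptr());
    for (int r = 0; r < len; ++r) {
      float acc = float(b2);
      for (int c = 0; c < C; ++c) acc += H(r, c) * w2f(c);
      const int rs = r - sh;
      const float ref = (rs >= 0 && rs < len) ? float(R(rs, s)) : 0.0f;
      const float e = acc - ref;
      loss += double(e) * double(e);
      dpre(r) = 2.0f * scale * e;
    }
    for (int c = 0; c < C; ++c) {
      float accw = 0.0f, accb = 0.0f;
      const float wc = w2f(c);
      for (int r = 0; r < len; ++r) {
        const float h = H(r, c);
        accw += h * dpre(r);
        // relu derivative: H > 0 iff pre-activation > 0 (bias included)
        const float d = (h > 0.0f) ? dpre(r) * wc : 0.0f;
        dH(r, c) = d;
        accb += d;
      }
      dw2(c) += accw;
      db1(c) += accb;
    }
    db2 += accu(dpre);
    roi_conv_dw(xp.memptr(), len, dH.memptr(), k, C, dW1.memptr());
  }
  loss *= scale;

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("dW1") = conv_to<mat>::from(dW1),
    Rcpp::Named("db1") = conv_to<vec>::from(db1),
    Rcpp::Named("dw2") = conv_to<vec>::from(dw2),
    Rcpp::Named("db2") = db2);
}

// ---------------------------------------------------------------------------
// Diameter tracker: 5 x [same-width conv + batch-norm + ReLU], flatten,
// FC(300) + ReLU + dropout, FC(64) + ReLU + dropout, FC(1) + sigmoid,
// scaled by the window width to give samples. Huber loss in sample units.
// ---------------------------------------------------------------------------

struct TrackerParams {
  std::vector<fmat> W;                  // conv weights (k*in_ch x out_ch)
  std::vector<std::vector<fmat>> Wt;    // per-tap (in_ch x out_ch) slices
  std::vector<fvec> Wk;                 // [t][c][o] packs (avx path)
  std::vector<fvec> Wrev;               // [t][o][c] reversed packs (dX)
  std::vector<fvec> b, g, be;           // conv bias, bn gamma, bn beta
  fmat F1, F2, F3;                      // fc weights
  fvec c1, c2, c3;                      // fc biases
  int k;
};

static TrackerParams unpack(const Rcpp::List& params) {
  TrackerParams P;
  Rcpp::List conv = params["conv"], fc = params["fc"];
  P.k = Rcpp::as<int>(params["kernel"]);
  for (int l = 0; l < conv.size(); ++l) {
    Rcpp::List cl = conv[l];
    P.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(cl["W"])));
    P.b.push_back(conv_to<fvec>::from(Rcpp::as<vec>(cl["b"])));
    P.g.push_back(conv_to<fvec>::from(Rcpp::as<vec>(cl["gamma"])));
    P.be.push_back(conv_to<fvec>::from(Rcpp::as<vec>(cl["beta"])));
    const fmat& W = P.W.back();
    const int ci = W.n_rows / P.k, co = W.n_cols;
    std::vector<fmat> taps(P.k);
    for (int t = 0; t < P.k; ++t) {
      taps[t].set_size(ci, co);
      for (int c = 0; c < ci; ++c) taps[t].row(c) = W.row(c * P.k + t);
    }
    P.Wt.push_back(std::move(taps));
    fvec wk(P.k * ci * co), wrev(P.k * co * ci);
    for (int t = 0; t < P.k; ++t)
      for (int c = 0; c < ci; ++c)
        for (int o = 0; o < co; ++o) {
          wk[(t * ci + c) * co + o] = W(c * P.k + t, o);
          wrev[(t * co + o) * ci + c] = W(c * P.k + (P.k - 1 - t), o);
        }
    P.Wk.push_back(std::move(wk));
    P.Wrev.push_back(std::move(wrev));
  }
  Rcpp::List f1 = fc[0], f2 = fc[1], f3 = fc[2];
  P.F1 = conv_to<fmat>::from(Rcpp::as<mat>(f1["W"]));
  P.c1 = conv_to<fvec>::from(Rcpp::as<vec>(f1["b"]));
  P.F2 = conv_to<fmat>::from(Rcpp::as<mat>(f2["W"]));
  P.c2 = conv_to<fvec>::from(Rcpp::as<vec>(f2["b"]));
  P.F3 = conv_to<fmat>::from(Rcpp::as<mat>(f3["W"]));
  P.c3 = conv_to<fvec>::from(Rcpp::as<vec>(f3["b"]));
  return P;
}

struct BatchGeom {
  int len, half, lenp, B, R;   // R = B * lenp (valid + guard rows)
};

// zero the guard rows; row0 is the offset of the first sample's block
// (0 for plain (R x C) matrices, `half` for margin matrices)
static void zero_guards_at(fmat& A, const int row0, const BatchGeom& G) {
  for (uword c = 0; c < A.n_cols; ++c) {
    float* col = A.colptr(c) + row0;
    for (int s = 0; s < G.B; ++s) {
      std::memset(col + s * G.lenp, 0, G.half * sizeof(float));
      std::memset(col + s * G.lenp + G.half + G.len, 0,
                  G.half * sizeof(float));
    }
  }
}

static void zero_guards(fmat& A, const BatchGeom& G) {
  zero_guards_at(A, 0, G);
}

static const int CONV_CHUNK = 4096;   // rows per GEMM chunk (cache blocking)

// Z (R x co) = conv bias + sum_t shift_t(Aext) * W_t; Aext has margin rows
static void conv_fwd(const fmat& Aext, const TrackerParams& P, const int l,
                     fmat& Z, const BatchGeom& G) {
  const std::vector<fmat>& Wt = P.Wt[l];
  const int k = Wt.size(), ci = Wt[0].n_rows, co = Wt[0].n_cols;
  Z.set_size(G.R, co);
  if (use_avx512() &&
      lt_conv_fwd_avx(Aext.memptr(), Aext.n_rows, P.Wk[l].memptr(), k, ci,
                      co, P.b[l].memptr(), Z.memptr(), G.R, G.R)) {
    return;
  }
  for (int c = 0; c < co; ++c) Z.col(c).fill(P.b[l](c));
  for (int r0 = 0; r0 < G.R; r0 += CONV_CHUNK) {
    const int m = std::min(CONV_CHUNK, G.R - r0);
    for (int t = 0; t < k; ++t)
      sgemm('N', 'N', m, co, ci, 1.0f, Aext.memptr() + r0 + t, Aext.n_rows,
            Wt[t].memptr(), ci, 1.0f, Z.memptr() + r0, G.R);
  }
}

// dAext (R + 2*half x ci) = sum_t shiftback_t(dZ * W_t')
static fmat conv_dx(const fmat& dZ, const TrackerParams& P, const int l,
                    const BatchGeom& G) {
  const std::vector<fmat>& Wt = P.Wt[l];
  const int k = Wt.size(), ci = Wt[0].n_rows, co = Wt[0].n_cols;
  if (use_avx512() && ci % 4 == 0) {
    // the adjoint of a same-width conv is a same-width conv of the
    // zero-extended gradient with the tap-reversed transposed weights
    fmat dZext(G.R + 2 * (k - 1), co, fill::zeros);
    dZext.rows(k - 1, k - 2 + G.R) = dZ;
    fmat dAext(G.R + 2 * G.half, ci);
    if (lt_conv_fwd_avx(dZext.memptr(), dZext.n_rows, P.Wrev[l].memptr(),
                        k, co, ci, nullptr, dAext.memptr(), dAext.n_rows,
                        G.R + 2 * G.half))
      return dAext;
  }
  fmat dAext(G.R + 2 * G.half, ci, fill::zeros);
  for (int r0 = 0; r0 < G.R; r0 += CONV_CHUNK) {
    const int m = std::min(CONV_CHUNK, G.R - r0);
    for (int t = 0; t < k; ++t)
      sgemm('N', 'T', m, ci, co, 1.0f, dZ.memptr() + r0, G.R,
            Wt[t].memptr(), ci, 1.0f, dAext.memptr() + r0 + t, dAext.n_rows);
  }
  return dAext;
}

// dW in the (k*ci x co) layout, row c*k + t; row-chunked so the A / dZ
// chunks stay cache resident across the taps
static fmat conv_dw(const fmat& Aext, const fmat& dZ, const int k,
                    const BatchGeom& G) {
  const int ci = Aext.n_cols, co = dZ.n_cols;
  if (use_avx512()) {
    fmat dZt(co, G.R);
    lt_transpose_avx(dZ.memptr(), G.R, G.R, co, dZt.memptr());
    fvec dWk(size_t(k) * ci * co);
    if (lt_conv_dw_avx(Aext.memptr(), Aext.n_rows, dZt.memptr(), k, ci, co,
                       dWk.memptr(), G.R)) {
      fmat dW(k * ci, co);
      for (int t = 0; t < k; ++t)
        for (int c = 0; c < ci; ++c)
          for (int o = 0; o < co; ++o)
            dW(c * k + t, o) = dWk[(t * ci + c) * co + o];
      return dW;
    }
  }
  std::vector<fmat> dWt(k, fmat(ci, co, fill::zeros));
  for (int r0 = 0; r0 < G.R; r0 += CONV_CHUNK) {
    const int m = std::min(CONV_CHUNK, G.R - r0);
    for (int t = 0; t < k; ++t)
      sgemm('T', 'N', ci, co, m, 1.0f, Aext.memptr() + r0 + t, Aext.n_rows,
            dZ.memptr() + r0, G.R, 1.0f, dWt[t].memptr(), ci);
  }
  fmat dW(k * ci, co);
  for (int t = 0; t < k; ++t)
    for (int c = 0; c < ci; ++c) dW.row(c * k + t) = dWt[t].row(c);
  return dW;
}

// pack input frames (len x B, double) into guard-row layout with margin
static fmat pack_input(const mat& X, const BatchGeom& G) {
  fmat out(G.R + 2 * G.half, 1, fill::zeros);
  for (int s = 0; s < G.B; ++s) {
    float* dst = out.memptr() + G.half + s * G.lenp + G.half;
    const double* src = X.colptr(s);
    for (int i = 0; i < G.len; ++i) dst[i] = float(src[i]);
  }
  return out;
}

// column-wise sum and sum of squares (guards are zero; caller corrects N)
static void col_moments(const fmat& Z, const fvec& ones, fvec& s1, fvec& s2) {
  const int n = Z.n_rows, C = Z.n_cols;
  s1.set_size(C); s2.set_size(C);
  for (int c = 0; c < C; ++c) {
    const float* z = Z.colptr(c);
    s1(c) = sdot(n, z, ones.memptr());
    s2(c) = sdot(n, z, z);
  }
}

static inline float relu_f(float v) { return v > 0.0f ? v : 0.0f; }

// d[r] <- 0 where y[r] <= 0, branchless so it vectorizes
LT_MULTIVER
static void relu_mask_col(float* __restrict d, const float* __restrict y,
                          const int n) {
  for (int r = 0; r < n; ++r) d[r] *= (y[r] > 0.0f) ? 1.0f : 0.0f;
}

// dZ = (iv/N) * (N * dA * g - t1 - zhat * t2)
LT_MULTIVER
static void bn_backward_col(float* __restrict o, const float* __restrict d,
                            const float* __restrict zh, const int n,
                            const float iv, const float gg, const float N,
                            const float t1, const float t2) {
  const float a = iv * gg, b = -(iv / N) * t1, c = -(iv / N) * t2;
  for (int r = 0; r < n; ++r) o[r] = a * d[r] + b + c * zh[r];
}

// zhat and relu(bn) outputs in one pass
LT_MULTIVER
static void bn_forward_col(const float* __restrict z, float* __restrict zh,
                           float* __restrict y, const int n, const float m,
                           const float iv, const float gg, const float bb) {
  for (int r = 0; r < n; ++r) {
    const float h = (z[r] - m) * iv;
    zh[r] = h;
    const float v = h * gg + bb;
    y[r] = v > 0.0f ? v : 0.0f;
  }
}

// [[Rcpp::export]]
arma::vec cpp_tracker_predict(const arma::mat& X, const Rcpp::List& params,
                              const Rcpp::List& running) {
  TrackerParams P = unpack(params);
  const int len = X.n_rows, B = X.n_cols, half = P.k / 2;
  const BatchGeom G{len, half, len + 2 * half, B, B * (len + 2 * half)};
  Rcpp::List rmu = running["mean"], rvar = running["var"];

  fmat Aext = pack_input(X, G);
  fmat Z;
  for (size_t l = 0; l < P.W.size(); ++l) {
    conv_fwd(Aext, P, l, Z, G);
    const fvec mu = conv_to<fvec>::from(Rcpp::as<vec>(rmu[l]));
    const fvec var_ = conv_to<fvec>::from(Rcpp::as<vec>(rvar[l]));
    fmat Ynext(G.R + 2 * half, Z.n_cols, fill::zeros);
    for (uword c = 0; c < Z.n_cols; ++c) {
      const float a = P.g[l](c) / std::sqrt(var_(c) + 1e-5f);
      const float b0 = P.be[l](c) - mu(c) * a;
      const float* z = Z.colptr(c);
      float* y = Ynext.colptr(c) + half;
      for (int r = 0; r < G.R; ++r) y[r] = relu_f(z[r] * a + b0);
    }
    // restore guard zeros (the affine shift filled them with relu(b0))
    zero_guards_at(Ynext, half, G);
    Aext = std::move(Ynext);
  }
  const int ch = P.W.back().n_cols;
  fmat Af(len * ch, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < ch; ++c)
      std::memcpy(Af.colptr(s) + c * len,
                  Aext.colptr(c) + half + s * G.lenp + half,
                  len * sizeof(float));
  fmat H1 = P.F1 * Af; H1.each_col() += P.c1;
  H1.transform([](float v) { return relu_f(v); });
  fmat H2 = P.F2 * H1; H2.each_col() += P.c2;
  H2.transform([](float v) { return relu_f(v); });
  frowvec z3 = P.F3 * H2 + P.c3(0);
  vec out(B);
  for (int s = 0; s < B; ++s)
    out(s) = double(len) / (1.0 + std::exp(-double(z3(s))));
  return out;
}

// one training step's forward + backward; gradients returned, parameter
// updates (Adam) done on the R side. Dropout masks are pre-scaled
// 0/(1/(1-p)) matrices generated from the R RNG.
// [[Rcpp::export]]
Rcpp::List cpp_tracker_grad(const arma::mat& X, const arma::vec& target,
                            const Rcpp::List& params, const Rcpp::List& running,
                            const double momentum, const double delta,
                            const arma::mat& drop1, const arma::mat& drop2) {
  TrackerParams P = unpack(params);
  const int len = X.n_rows, B = X.n_cols, half = P.k / 2;
  const size_t L = P.W.size();
  const BatchGeom G{len, half, len + 2 * half, B, B * (len + 2 * half)};
  const float Nreal = float(len) * float(B);
  Rcpp::List rmu = running["mean"], rvar = running["var"];

  std::vector<fmat> Aexts(L + 1);      // layer inputs/outputs (with margin)
  std::vector<fmat> Zhat(L);           // normalized pre-activations
  std::vector<fvec> invstds(L);
  Rcpp::List new_mu(L), new_var(L);

  Aexts[0] = pack_input(X, G);
  const fvec ones(G.R, fill::ones);
  fmat Z;
  for (size_t l = 0; l < L; ++l) {
    conv_fwd(Aexts[l], P, l, Z, G);
    // bias polluted the guard rows; reset them before the statistics
    zero_guards(Z, G);
    const int C = Z.n_cols;
    fvec s1, s2;
    col_moments(Z, ones, s1, s2);
    fvec mu(C), var_(C), invstd(C);
    for (int c = 0; c < C; ++c) {
      // guard rows are zero so s1/s2 are sums over the valid rows only
      mu(c) = s1(c) / Nreal;
      var_(c) = s2(c) / Nreal - mu(c) * mu(c);
      invstd(c) = 1.0f / std::sqrt(var_(c) + 1e-5f);
    }
    vec old_mu = Rcpp::as<vec>(rmu[l]), old_var = Rcpp::as<vec>(rvar[l]);
    new_mu[l] = Rcpp::wrap((1.0 - momentum) * old_mu +
                           momentum * conv_to<vec>::from(mu));
    new_var[l] = Rcpp::wrap((1.0 - momentum) * old_var +
                            momentum * conv_to<vec>::from(var_));
    fmat Zh(G.R, C);
    fmat Ynext(G.R + 2 * half, C, fill::zeros);
    for (int c = 0; c < C; ++c)
      bn_forward_col(Z.colptr(c), Zh.colptr(c), Ynext.colptr(c) + half,
                     G.R, mu(c), invstd(c), P.g[l](c), P.be[l](c));
    // restore guard zeros in the next layer's input
    zero_guards_at(Ynext, half, G);
    Zhat[l] = std::move(Zh);
    invstds[l] = invstd;
    Aexts[l + 1] = std::move(Ynext);
  }

  // flatten valid rows
  const int ch = P.W.back().n_cols;
  const int flat = len * ch;
  fmat Af(flat, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < ch; ++c)
      std::memcpy(Af.colptr(s) + c * len,
                  Aexts[L].colptr(c) + half + s * G.lenp + half,
                  len * sizeof(float));

  const fmat D1 = conv_to<fmat>::from(drop1);
  const fmat D2 = conv_to<fmat>::from(drop2);
  fmat Z1 = P.F1 * Af; Z1.each_col() += P.c1;
  fmat H1 = Z1;
  H1.transform([](float v) { return relu_f(v); });
  H1 %= D1;
  fmat Z2 = P.F2 * H1; Z2.each_col() += P.c2;
  fmat H2 = Z2;
  H2.transform([](float v) { return relu_f(v); });
  H2 %= D2;
  frowvec z3 = P.F3 * H2 + P.c3(0);
  vec sig(B), pred(B);
  for (int s = 0; s < B; ++s) {
    sig(s) = 1.0 / (1.0 + std::exp(-double(z3(s))));
    pred(s) = double(len) * sig(s);
  }

  // Huber loss in sample units
  double loss = 0.0;
  vec dpred(B);
  for (int s = 0; s < B; ++s) {
    const double e = pred(s) - target(s), ae = std::fabs(e);
    loss += (ae <= delta) ? 0.5 * e * e : delta * (ae - 0.5 * delta);
    dpred(s) = ((ae <= delta) ? e : (e > 0 ? delta : -delta)) / double(B);
  }
  loss /= double(B);

  // head backward
  frowvec dz3(B);
  for (int s = 0; s < B; ++s)
    dz3(s) = float(dpred(s) * double(len) * sig(s) * (1.0 - sig(s)));
  fmat dF3 = dz3 * H2.t();
  fvec dc3(1); dc3(0) = accu(dz3);
  fmat dH2 = P.F3.t() * dz3;
  dH2 %= D2;
  for (uword i = 0; i < dH2.n_elem; ++i)
    if (Z2(i) <= 0.0f) dH2(i) = 0.0f;
  fmat dF2 = dH2 * H1.t();
  fvec dc2 = sum(dH2, 1);
  fmat dH1 = P.F2.t() * dH2;
  dH1 %= D1;
  for (uword i = 0; i < dH1.n_elem; ++i)
    if (Z1(i) <= 0.0f) dH1(i) = 0.0f;
  fmat dF1 = dH1 * Af.t();
  fvec dc1 = sum(dH1, 1);
  fmat dAf = P.F1.t() * dH1;

  // unflatten into guard layout
  fmat dA(G.R, ch, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < ch; ++c)
      std::memcpy(dA.colptr(c) + s * G.lenp + half,
                  dAf.colptr(s) + c * len, len * sizeof(float));

  Rcpp::List conv_grads(L);
  for (int l = int(L) - 1; l >= 0; --l) {
    const int C = dA.n_cols;
    // relu mask (branchless), then bn reductions via BLAS dots
    fvec dgamma(C), dbeta(C);
    for (int c = 0; c < C; ++c) {
      relu_mask_col(dA.colptr(c), Aexts[l + 1].colptr(c) + half, G.R);
      dgamma(c) = sdot(G.R, dA.colptr(c), Zhat[l].colptr(c));
      dbeta(c) = sdot(G.R, dA.colptr(c), ones.memptr());
    }
    fmat dZ(G.R, C);
    for (int c = 0; c < C; ++c) {
      const float iv = invstds[l](c), gg = P.g[l](c);
      bn_backward_col(dZ.colptr(c), dA.colptr(c), Zhat[l].colptr(c), G.R,
                      iv, gg, Nreal, dbeta(c) * gg, dgamma(c) * gg);
    }
    zero_guards(dZ, G);
    fvec db(C);
    for (int c = 0; c < C; ++c) db(c) = sdot(G.R, dZ.colptr(c), ones.memptr());

    fmat dW = conv_dw(Aexts[l], dZ, P.k, G);
    conv_grads[l] = Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(dW),
      Rcpp::Named("b") = conv_to<vec>::from(db),
      Rcpp::Named("gamma") = conv_to<vec>::from(dgamma),
      Rcpp::Named("beta") = conv_to<vec>::from(dbeta));
    if (l > 0) {
      fmat dAext = conv_dx(dZ, P, l, G);
      dA = dAext.rows(half, half + G.R - 1);
      zero_guards(dA, G);
    }
  }

  Rcpp::List fc_grads = Rcpp::List::create(
    Rcpp::List::create(Rcpp::Named("W") = conv_to<mat>::from(dF1),
                       Rcpp::Named("b") = conv_to<vec>::from(dc1)),
    Rcpp::List::create(Rcpp::Named("W") = conv_to<mat>::from(dF2),
                       Rcpp::Named("b") = conv_to<vec>::from(dc2)),
    Rcpp::List::create(Rcpp::Named("W") = conv_to<mat>::from(dF3),
                       Rcpp::Named("b") = conv_to<vec>::from(dc3)));

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("pred") = pred,
    Rcpp::Named("grads") = Rcpp::List::create(Rcpp::Named("conv") = conv_grads,
                                              Rcpp::Named("fc") = fc_grads),
    Rcpp::Named("running") = Rcpp::List::create(Rcpp::Named("mean") = new_mu,
                                                Rcpp::Named("var") = new_var));
}
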