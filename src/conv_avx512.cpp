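// AVX-512 microkernels for the tracker's narrow multi-channel 1-D
// convolutions. Compiled with -mavx512f (see Makevars target rule) and
// selected at run time; the BLAS tap path in kernels.cpp is the portable
// fallback (also used when a shape is outside these kernels' fast cases).
//
// Layout contract (same as kernels.cpp): activations are column-major
// (rows x channels) float matrices in the guard-row batch layout; the
// input of each layer carries margin rows so a tap shift is a pointer
// offset. Weights arrive packed as Wk[t][c][o] with o fastest.
//
// All loop bounds in the hot loops are compile-time constants: with
// runtime bounds gcc cannot keep the accumulator tiles in zmm registers
// and spills them, which costs an order of magnitude.

#include <cstring>
#include <algorithm>

#if defined(__x86_64__) && (defined(__GNUC__) || defined(__clang__))
#include <immintrin.h>

static const int K9 = 9;

// Z[r, o] = bias[o] + sum_{t,c} A[r + t, c] * Wk[(t*ci + c)*co + o];
// 64 rows x 4 output channels per register tile.
static void fwd_k9(const float* A, const int ldA, const float* Wk,
                   const int ci, const int co, const float* bias, float* Z,
                   const int ldZ, const int R) {
  const int RB = 64;
  int r = 0;
  for (; r + RB <= R; r += RB) {
    for (int o0 = 0; o0 < co; o0 += 4) {
      __m512 acc[4][4];
      for (int j = 0; j < 4; ++j) {
        const __m512 b = _mm512_set1_ps(bias ? bias[o0 + j] : 0.0f);
        acc[j][0] = b; acc[j][1] = b; acc[j][2] = b; acc[j][3] = b;
      }
      for (int t = 0; t < K9; ++t)
        for (int c = 0; c < ci; ++c) {
          const float* a = A + r + t + c * ldA;
          const __m512 a0 = _mm512_loadu_ps(a);
          const __m512 a1 = _mm512_loadu_ps(a + 16);
          const __m512 a2 = _mm512_loadu_ps(a + 32);
          const __m512 a3 = _mm512_loadu_ps(a + 48);
          const float* w = Wk + (t * ci + c) * co + o0;
          for (int j = 0; j < 4; ++j) {
            const __m512 wv = _mm512_set1_ps(w[j]);
            acc[j][0] = _mm512_fmadd_ps(a0, wv, acc[j][0]);
            acc[j][1] = _mm512_fmadd_ps(a1, wv, acc[j][1]);
            acc[j][2] = _mm512_fmadd_ps(a2, wv, acc[j][2]);
            acc[j][3] = _mm512_fmadd_ps(a3, wv, acc[j][3]);
          }
        }
      for (int j = 0; j < 4; ++j) {
        float* z = Z + r + (o0 + j) * ldZ;
        _mm512_storeu_ps(z, acc[j][0]);
        _mm512_storeu_ps(z + 16, acc[j][1]);
        _mm512_storeu_ps(z + 32, acc[j][2]);
        _mm512_storeu_ps(z + 48, acc[j][3]);
      }
    }
  }
  for (; r < R; ++r)   // scalar tail
    for (int o = 0; o < co; ++o) {
      float acc = bias ? bias[o] : 0.0f;
      for (int t = 0; t < K9; ++t)
        for (int c = 0; c < ci; ++c)
          acc += A[r + t + c * ldA] * Wk[(t * ci + c) * co + o];
      Z[r + o * ldZ] = acc;
    }
}

bool lt_conv_fwd_avx(const float* A, int ldA, const float* Wk, int k,
                     int ci, int co, const float* bias, float* Z, int ldZ,
                     int R) {
  if (k != K9 || co % 4 != 0) return false;
  fwd_k9(A, ldA, Wk, ci, co, bias, Z, ldZ, R);
  return true;
}

// dW[(t*ci + c)*co + o] = sum_r A[r + t, c] * dZt[o + r*co]
// (dZt transposed, co x R, one gradient row contiguous per column).
template <int NV>   // co = 16 * NV
static void dw_k9(const float* A, const int ldA, const float* dZt,
                  const int ci, float* dWk, const int R) {
  const int co = 16 * NV;
  for (int c = 0; c < ci; ++c) {
    __m512 acc[K9][NV];
    for (int t = 0; t < K9; ++t)
      for (int v = 0; v < NV; ++v) acc[t][v] = _mm512_setzero_ps();
    const float* ac = A + c * ldA;
    for (int r = 0; r < R; ++r) {
      __m512 dz[NV];
      for (int v = 0; v < NV; ++v)
        dz[v] = _mm512_loadu_ps(dZt + size_t(r) * co + 16 * v);
      for (int t = 0; t < K9; ++t) {
        const __m512 a = _mm512_set1_ps(ac[r + t]);
        for (int v = 0; v < NV; ++v)
          acc[t][v] = _mm512_fmadd_ps(a, dz[v], acc[t][v]);
      }
    }
    for (int t = 0; t < K9; ++t)
      for (int v = 0; v < NV; ++v)
        _mm512_storeu_ps(dWk + (t * ci + c) * co + 16 * v, acc[t][v]);
  }
}

static void dw_k9_co8(const float* A, const int ldA, const float* dZt,
                      const int ci, float* dWk, const int R) {
  const int co = 8;
  for (int c = 0; c < ci; ++c) {
    __m256 acc[K9];
    for (int t = 0; t < K9; ++t) acc[t] = _mm256_setzero_ps();
    const float* ac = A + c * ldA;
    for (int r = 0; r < R; ++r) {
      const __m256 dz = _mm256_loadu_ps(dZt + size_t(r) * co);
      for (int t = 0; t < K9; ++t)
        acc[t] = _mm256_fmadd_ps(_mm256_set1_ps(ac[r + t]), dz, acc[t]);
    }
    for (int t = 0; t < K9; ++t)
      _mm256_storeu_ps(dWk + (t * ci + c) * co, acc[t]);
  }
}

bool lt_conv_dw_avx(const float* A, int ldA, const float* dZt, int k,
                    int ci, int co, float* dWk, int R) {
  if (k != K9) return false;
  if (co == 32) dw_k9<2>(A, ldA, dZt, ci, dWk, R);
  else if (co == 16) dw_k9<1>(A, ldA, dZt, ci, dWk, R);
  else if (co == 8) dw_k9_co8(A, ldA, dZt, ci, dWk, R);
  else return false;
  return true;
}

// transpose a (R x co) column-major block into (co x R) column-major
void lt_transpose_avx(const float* Z, int ldZ, int R, int co, float* Zt) {
  const int BR = 128;
  for (int r0 = 0; r0 < R; r0 += BR) {
    const int m = std::min(BR, R - r0);
    for (int o = 0; o < co; ++o) {
      const float* src = Z + r0 + size_t(o) * ldZ;
      float* dst = Zt + size_t(r0) * co + o;
      for (int i = 0; i < m; ++i) dst[size_t(i) * co] = src[i];
    }
  }
}

#else  // non-x86 or unsupported compiler: stubs, never selected

bool lt_conv_fwd_avx(const float*, int, const float*, int, int, int,
                     const float*, float*, int, int) { return false; }
bool lt_conv_dw_avx(const float*, int, const float*, int, int, int, float*,
                    int) { return false; }
void lt_transpose_avx(const float*, int, int, int, float*) {}

#endif
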