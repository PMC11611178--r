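// Raw BLAS entry points, isolated here so the Fortran declarations do not
// clash with the ones RcppArmadillo pulls in.

extern "C" {
void sgemm_(const char*, const char*, const int*, const int*, const int*,
            const float*, const float*, const int*, const float*, const int*,
            const float*, float*, const int*);
float sdot_(const int*, const float*, const int*, const float*, const int*);
}

void lt_sgemm(char ta, char tb, int m, int n, int k, float alpha,
              const float* A, int lda, const float* B, int ldb, float beta,
              float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

float lt_sdot(int n, const float* x, const float* y) {
  const int one = 1;
  return sdot_(&n, x, &one, y, &one);
}
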