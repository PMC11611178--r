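PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)

conv_avx512.o: CXXFLAGS += -mavx512f -mavx512vl -mfma -O3
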