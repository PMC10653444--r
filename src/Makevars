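# hot loops in kernels.cpp need vectorization; the toolchain default
# (-O2 -march=nocona) predates AVX/FMA and costs ~6x on the conv kernels.
# Makevars is included before Makeconf, so a plain assignment would be
# clobbered; override keeps these flags in effect.
override CXXFLAGS = -O3 -march=native -funroll-loops -fPIC -fvisibility-inlines-hidden
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
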