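PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)

# The conv3d kernels are compute-bound AXPY/dot loop nests; build them with
# full optimisation and, where the build machine supports it, AVX2 (flags
# appended after ALL_CXXFLAGS so they take precedence over the defaults).
KERNEL_OPT = -O3 $(shell grep -q avx2 /proc/cpuinfo 2>/dev/null && echo -march=x86-64-v3)

# keep the shared object the default goal despite the explicit rule below
all: $(SHLIB)

nn_kernels.o: nn_kernels.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) $(KERNEL_OPT) -c nn_kernels.cpp -o nn_kernels.o
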