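// Low-level 3D convolution / pooling kernels for the synthesis and
// classification networks.  Feature maps are stored channel-last, i.e. an
// R array of dim (X, Y, Z, C); a map is viewed as a (X*Y*Z) x C column-major
// matrix so that every convolution reduces to BLAS GEMM calls.
//
// Two convolution paths are provided:
//   * conv3s1_*  -- kernel 3, stride 1, zero pad 1 (the generator's
//     workhorse).  Implemented without materialising an im2col matrix: the input
//     is copied once into a zero-padded buffer and the convolution becomes
//     27 shifted-view GEMM accumulations.
//   * conv3d_*   -- generic kernel/stride/pad via explicit im2col.
//
// All kernels can run in single precision (default, fast) or double
// precision (used by the exact-invertibility checks).  Inputs and outputs
// are always R doubles; conversion happens inside.

#include <RcppArmadillo.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

extern "C" {
void sgemm_(const char *, const char *, const int *, const int *, const int *,
            const float *, const float *, const int *, const float *,
            const int *, const float *, float *, const int *);
void dgemm_(const char *, const char *, const int *, const int *, const int *,
            const double *, const double *, const int *, const double *,
            const int *, const double *, double *, const int *);
}


template <typename T>
static void gemm(char ta, char tb, int m, int n, int k, T alpha, const T *A,
                 int lda, const T *B, int ldb, T beta, T *C, int ldc);

template <>
void gemm<float>(char ta, char tb, int m, int n, int k, float alpha,
                 const float *A, int lda, const float *B, int ldb, float beta,
                 float *C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

template <>
void gemm<double>(char ta, char tb, int m, int n, int k, double alpha,
                  const double *A, int lda, const double *B, int ldb,
                  double beta, double *C, int ldc) {
  dgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// ---- helpers ---------------------------------------------------------------

// copy x (X,Y,Z,C double) into zero-padded (X+2,Y+2,Z+2,C) buffer of T
template <typename T>
static void pad1_copy(const double *x, int X, int Y, int Z, int C,
                      std::vector<T> &P) {
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  const size_t Vp = (size_t)Xp * Yp * Zp;
  P.assign(Vp * C, T(0));
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        const double *src = x + (size_t)X * (y + (size_t)Y * (z + (size_t)Z * c));
        T *dst = P.data() + Vp * c + 1 + (size_t)Xp * ((y + 1) + (size_t)Yp * (z + 1));
        for (int i = 0; i < X; ++i) dst[i] = (T)src[i];
      }
}

// extract interior rows of padded (Vp x C) buffer into double (X,Y,Z,C)
template <typename T>
static void unpad1_copy(const std::vector<T> &P, int X, int Y, int Z, int C,
                        double *out) {
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  const size_t Vp = (size_t)Xp * Yp * Zp;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        const T *src = P.data() + Vp * c + 1 + (size_t)Xp * ((y + 1) + (size_t)Yp * (z + 1));
        double *dst = out + (size_t)X * (y + (size_t)Y * (z + (size_t)Z * c));
        for (int i = 0; i < X; ++i) dst[i] = (double)src[i];
      }
}

// ---- kernel-3 stride-1 pad-1 convolution ----------------------------------

// weight layout: w is (27*Cin) x Cout, row index = o*Cin + c with
// o = kx + 3*(ky + 3*kz), kx/ky/kz in 0..2 (offset = k - 1).
//
// Direct line-wise kernel: for every output x-line the 27*Cin contributions
// are accumulated as contiguous AXPY loops over the padded input, which the
// compiler vectorises; channel counts here are small, so BLAS GEMM overhead
// would dominate.
template <typename T>
static void conv3s1_fwd_t(const double *x, int X, int Y, int Z, int Cin,
                          const double *w, const double *b, int Cout,
                          double *out) {
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  const size_t Vp = (size_t)Xp * Yp * Zp;
  std::vector<T> P;
  pad1_copy<T>(x, X, Y, Z, Cin, P);
  std::vector<T> W((size_t)27 * Cin * Cout);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (T)w[i];
  const int ldw = 27 * Cin;
  const size_t V = (size_t)X * Y * Z;
  std::vector<T> acc((size_t)X);
  for (int co = 0; co < Cout; ++co) {
    double *yc = out + V * co;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        T *a = acc.data();
        for (int i = 0; i < X; ++i) a[i] = T(0);
        for (int ci = 0; ci < Cin; ++ci) {
          const T *pc = P.data() + Vp * ci;
          for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky) {
              const T *row = pc + (size_t)Xp * ((y + ky) + (size_t)Yp * (z + kz));
              for (int kx = 0; kx < 3; ++kx) {
                const int o = kx + 3 * (ky + 3 * kz);
                const T wv = W[(size_t)o * Cin + ci + (size_t)ldw * co];
                const T *src = row + kx;
                for (int i = 0; i < X; ++i) a[i] += wv * src[i];
              }
            }
        }
        double *dst = yc + (size_t)X * (y + (size_t)Y * z);
        const double bc = b[co];
        for (int i = 0; i < X; ++i) dst[i] = (double)a[i] + bc;
      }
  }
}

template <typename T>
static void conv3s1_bwd_t(const double *x, int X, int Y, int Z, int Cin,
                          const double *w, int Cout, const double *dy,
                          double *dx, double *dw, double *db) {
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  const size_t Vp = (size_t)Xp * Yp * Zp;
  const size_t V = (size_t)X * Y * Z;
  std::vector<T> P, dYpad;
  pad1_copy<T>(x, X, Y, Z, Cin, P);
  std::vector<T> W((size_t)27 * Cin * Cout);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (T)w[i];
  std::vector<T> dXpad(Vp * Cin, T(0));
  std::vector<T> dW((size_t)27 * Cin * Cout, T(0));
  std::vector<T> dline((size_t)X);
  const int ldw = 27 * Cin;
  for (int co = 0; co < Cout; ++co) {
    const double *dyc = dy + V * co;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        const double *dsrc = dyc + (size_t)X * (y + (size_t)Y * z);
        T *dl = dline.data();
        for (int i = 0; i < X; ++i) dl[i] = (T)dsrc[i];
        for (int ci = 0; ci < Cin; ++ci) {
          const T *pc = P.data() + Vp * ci;
          T *dxc = dXpad.data() + Vp * ci;
          for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky) {
              const size_t roff = (size_t)Xp * ((y + ky) + (size_t)Yp * (z + kz));
              const T *prow = pc + roff;
              T *dxrow = dxc + roff;
              for (int kx = 0; kx < 3; ++kx) {
                const int o = kx + 3 * (ky + 3 * kz);
                const size_t wi = (size_t)o * Cin + ci + (size_t)ldw * co;
                const T wv = W[wi];
                const T *__restrict__ psh = prow + kx;
                T *__restrict__ dxsh = dxrow + kx;
                T dot = T(0);
                for (int i = 0; i < X; ++i) dot += psh[i] * dl[i];
                for (int i = 0; i < X; ++i) dxsh[i] += wv * dl[i];
                dW[wi] += dot;
              }
            }
        }
      }
  }
  unpad1_copy<T>(dXpad, X, Y, Z, Cin, dx);
  for (size_t i = 0; i < dW.size(); ++i) dw[i] = (double)dW[i];
  for (int c = 0; c < Cout; ++c) {
    const double *src = dy + V * c;
    double s = 0;
    for (size_t i = 0; i < V; ++i) s += src[i];
    db[c] = s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3s1_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector w, NumericVector b, int cout,
                              bool single) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  NumericVector out((R_xlen_t)X * Y * Z * cout);
  if (single)
    conv3s1_fwd_t<float>(x.begin(), X, Y, Z, Cin, w.begin(), b.begin(), cout,
                         out.begin());
  else
    conv3s1_fwd_t<double>(x.begin(), X, Y, Z, Cin, w.begin(), b.begin(), cout,
                          out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_conv3s1_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                     int cout, NumericVector dy, bool single) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  NumericVector dx((R_xlen_t)X * Y * Z * Cin);
  NumericVector dw((R_xlen_t)27 * Cin * cout);
  NumericVector db(cout);
  if (single)
    conv3s1_bwd_t<float>(x.begin(), X, Y, Z, Cin, w.begin(), cout, dy.begin(),
                         dx.begin(), dw.begin(), db.begin());
  else
    conv3s1_bwd_t<double>(x.begin(), X, Y, Z, Cin, w.begin(), cout, dy.begin(),
                          dx.begin(), dw.begin(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- generic im2col convolution --------------------------------------------

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// im2col matrix: (Xo*Yo*Zo) x (k^3*Cin), column j = o*Cin + c,
// o = kx + k*(ky + k*kz)
template <typename T>
static void im2col(const double *x, int X, int Y, int Z, int Cin, int k, int s,
                   int p, std::vector<T> &M, int &Xo, int &Yo, int &Zo) {
  Xo = out_extent(X, k, s, p);
  Yo = out_extent(Y, k, s, p);
  Zo = out_extent(Z, k, s, p);
  const size_t Vo = (size_t)Xo * Yo * Zo;
  M.assign(Vo * k * k * k * Cin, T(0));
  for (int kz = 0; kz < k; ++kz)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int o = kx + k * (ky + k * kz);
        // valid output range along x, so the inner copy is check-free
        int ox_lo = 0, ox_hi = Xo;
        while (ox_lo < Xo && ox_lo * s + kx - p < 0) ++ox_lo;
        while (ox_hi > ox_lo && (ox_hi - 1) * s + kx - p >= X) --ox_hi;
        for (int c = 0; c < Cin; ++c) {
          T *col = M.data() + Vo * ((size_t)o * Cin + c);
          const double *xc = x + (size_t)X * Y * Z * c;
          for (int oz = 0; oz < Zo; ++oz) {
            const int iz = oz * s + kz - p;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < Yo; ++oy) {
              const int iy = oy * s + ky - p;
              if (iy < 0 || iy >= Y) continue;
              T *dst = col + (size_t)Xo * (oy + (size_t)Yo * oz);
              const double *src = xc + (size_t)X * (iy + (size_t)Y * iz) +
                                  kx - p;
              for (int ox = ox_lo; ox < ox_hi; ++ox)
                dst[ox] = (T)src[ox * s];
            }
          }
        }
      }
}

// adjoint of im2col: scatter-add columns back into dx
template <typename T>
static void col2im(const std::vector<T> &M, int X, int Y, int Z, int Cin,
                   int k, int s, int p, double *dx) {
  const int Xo = out_extent(X, k, s, p);
  const int Yo = out_extent(Y, k, s, p);
  const int Zo = out_extent(Z, k, s, p);
  const size_t Vo = (size_t)Xo * Yo * Zo;
  std::memset(dx, 0, sizeof(double) * (size_t)X * Y * Z * Cin);
  for (int kz = 0; kz < k; ++kz)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int o = kx + k * (ky + k * kz);
        int ox_lo = 0, ox_hi = Xo;
        while (ox_lo < Xo && ox_lo * s + kx - p < 0) ++ox_lo;
        while (ox_hi > ox_lo && (ox_hi - 1) * s + kx - p >= X) --ox_hi;
        for (int c = 0; c < Cin; ++c) {
          const T *col = M.data() + Vo * ((size_t)o * Cin + c);
          double *xc = dx + (size_t)X * Y * Z * c;
          for (int oz = 0; oz < Zo; ++oz) {
            const int iz = oz * s + kz - p;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < Yo; ++oy) {
              const int iy = oy * s + ky - p;
              if (iy < 0 || iy >= Y) continue;
              const T *src = col + (size_t)Xo * (oy + (size_t)Yo * oz);
              double *dst = xc + (size_t)X * (iy + (size_t)Y * iz) + kx - p;
              for (int ox = ox_lo; ox < ox_hi; ++ox)
                dst[ox * s] += (double)src[ox];
            }
          }
        }
      }
}

template <typename T>
static void conv3d_fwd_t(const double *x, int X, int Y, int Z, int Cin,
                         const double *w, const double *b, int Cout, int k,
                         int s, int p, double *out, int *odim) {
  int Xo, Yo, Zo;
  std::vector<T> M;
  im2col<T>(x, X, Y, Z, Cin, k, s, p, M, Xo, Yo, Zo);
  const int Vo = Xo * Yo * Zo;
  const int K = k * k * k * Cin;
  std::vector<T> W((size_t)K * Cout);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (T)w[i];
  std::vector<T> Yv((size_t)Vo * Cout);
  gemm<T>('N', 'N', Vo, Cout, K, T(1), M.data(), Vo, W.data(), K, T(0),
          Yv.data(), Vo);
  for (int c = 0; c < Cout; ++c) {
    double *dst = out + (size_t)Vo * c;
    const T *src = Yv.data() + (size_t)Vo * c;
    const double bc = b[c];
    for (int i = 0; i < Vo; ++i) dst[i] = (double)src[i] + bc;
  }
  odim[0] = Xo; odim[1] = Yo; odim[2] = Zo;
}

template <typename T>
static void conv3d_bwd_t(const double *x, int X, int Y, int Z, int Cin,
                         const double *w, int Cout, int k, int s, int p,
                         const double *dy, double *dx, double *dw,
                         double *db) {
  int Xo, Yo, Zo;
  std::vector<T> M;
  im2col<T>(x, X, Y, Z, Cin, k, s, p, M, Xo, Yo, Zo);
  const int Vo = Xo * Yo * Zo;
  const int K = k * k * k * Cin;
  std::vector<T> W((size_t)K * Cout), dY((size_t)Vo * Cout);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (T)w[i];
  for (size_t i = 0; i < dY.size(); ++i) dY[i] = (T)dy[i];
  // dW = M^T dY
  std::vector<T> dWv((size_t)K * Cout);
  gemm<T>('T', 'N', K, Cout, Vo, T(1), M.data(), Vo, dY.data(), Vo, T(0),
          dWv.data(), K);
  for (size_t i = 0; i < dWv.size(); ++i) dw[i] = (double)dWv[i];
  // dM = dY W^T, then scatter back
  std::vector<T> dM((size_t)Vo * K);
  gemm<T>('N', 'T', Vo, K, Cout, T(1), dY.data(), Vo, W.data(), K, T(0),
          dM.data(), Vo);
  col2im<T>(dM, X, Y, Z, Cin, k, s, p, dx);
  for (int c = 0; c < Cout; ++c) {
    const double *src = dy + (size_t)Vo * c;
    double sum = 0;
    for (int i = 0; i < Vo; ++i) sum += src[i];
    db[c] = sum;
  }
}

// [[Rcpp::export]]
List cpp_conv3d_fwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    NumericVector b, int cout, int k, int stride, int pad,
                    bool single) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  NumericVector out((R_xlen_t)Xo * Yo * Zo * cout);
  int odim[3];
  if (single)
    conv3d_fwd_t<float>(x.begin(), X, Y, Z, Cin, w.begin(), b.begin(), cout, k,
                        stride, pad, out.begin(), odim);
  else
    conv3d_fwd_t<double>(x.begin(), X, Y, Z, Cin, w.begin(), b.begin(), cout,
                         k, stride, pad, out.begin(), odim);
  return List::create(_["y"] = out,
                      _["dim"] = IntegerVector::create(odim[0], odim[1],
                                                       odim[2], cout));
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    int cout, int k, int stride, int pad, NumericVector dy,
                    bool single) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  NumericVector dx((R_xlen_t)X * Y * Z * Cin);
  NumericVector dw((R_xlen_t)k * k * k * Cin * cout);
  NumericVector db(cout);
  if (single)
    conv3d_bwd_t<float>(x.begin(), X, Y, Z, Cin, w.begin(), cout, k, stride,
                        pad, dy.begin(), dx.begin(), dw.begin(), db.begin());
  else
    conv3d_bwd_t<double>(x.begin(), X, Y, Z, Cin, w.begin(), cout, k, stride,
                         pad, dy.begin(), dx.begin(), dw.begin(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- 2x2x2 max pooling ------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const R_xlen_t Vo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector y(Vo * C);
  IntegerVector idx(Vo * C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (size_t)X * Y * Z * c;
    double *yc = y.begin() + (size_t)Vo * c;
    int *ic = idx.begin() + (size_t)Vo * c;
    for (int oz = 0; oz < Zo; ++oz)
      for (int oy = 0; oy < Yo; ++oy)
        for (int ox = 0; ox < Xo; ++ox) {
          double best = -HUGE_VAL;
          size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx_ = 0; dx_ < 2; ++dx_) {
                const size_t ii = (size_t)(2 * ox + dx_) +
                                  (size_t)X * ((2 * oy + dy_) +
                                               (size_t)Y * (2 * oz + dz));
                if (xc[ii] > best) { best = xc[ii]; besti = ii; }
              }
          const size_t oo = (size_t)ox + (size_t)Xo * (oy + (size_t)Yo * oz);
          yc[oo] = best;
          ic[oo] = (int)besti;
        }
  }
  return List::create(_["y"] = y,
                      _["dim"] = IntegerVector::create(Xo, Yo, Zo, C),
                      _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  const R_xlen_t Vo = dy.size() / C;
  NumericVector dx(V * C);
  for (int c = 0; c < C; ++c) {
    double *dxc = dx.begin() + (size_t)V * c;
    const double *dyc = dy.begin() + (size_t)Vo * c;
    const int *ic = idx.begin() + (size_t)Vo * c;
    for (R_xlen_t i = 0; i < Vo; ++i) dxc[ic[i]] += dyc[i];
  }
  return dx;
}

// ---- instance normalisation -------------------------------------------------

// y = (x - mean_c) / sqrt(var_c + eps) per channel; returns y and 1/sd
// [[Rcpp::export]]
List cpp_inorm_fwd(NumericVector x, IntegerVector xdim, double eps) {
  const int C = xdim[3];
  const R_xlen_t V = (R_xlen_t)xdim[0] * xdim[1] * xdim[2];
  NumericVector y(V * C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + V * c;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < V; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double mu = s / V;
    const double var = s2 / V - mu * mu;
    const double iv = 1.0 / std::sqrt(var + eps);
    inv[c] = iv;
    double *yc = y.begin() + V * c;
    for (R_xlen_t i = 0; i < V; ++i) yc[i] = (xc[i] - mu) * iv;
  }
  return List::create(_["y"] = y, _["inv"] = inv);
}

// dx = inv * (dy - mean(dy) - xhat * mean(dy * xhat)), xhat == y
// [[Rcpp::export]]
NumericVector cpp_inorm_bwd(NumericVector y, NumericVector inv,
                            NumericVector dy, IntegerVector xdim) {
  const int C = xdim[3];
  const R_xlen_t V = (R_xlen_t)xdim[0] * xdim[1] * xdim[2];
  NumericVector dx(V * C);
  for (int c = 0; c < C; ++c) {
    const double *yc = y.begin() + V * c;
    const double *dc = dy.begin() + V * c;
    double m1 = 0, m2 = 0;
    for (R_xlen_t i = 0; i < V; ++i) { m1 += dc[i]; m2 += dc[i] * yc[i]; }
    m1 /= V; m2 /= V;
    const double iv = inv[c];
    double *xc = dx.begin() + V * c;
    for (R_xlen_t i = 0; i < V; ++i)
      xc[i] = iv * (dc[i] - m1 - yc[i] * m2);
  }
  return dx;
}
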