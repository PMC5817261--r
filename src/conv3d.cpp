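// Low-level kernels for 3D convolutional networks.
//
// Volumes are R arrays with dim (nx, ny, nz, C), column-major.  A 3x3x3
// same-padded convolution with stride s is expressed as im2col followed by
// a BLAS gemm on the R side; col2im is its exact adjoint, which doubles as
// the forward pass of the stride-2 transposed convolution used for
// upsampling.  Keeping the gemm in R (BLAS) and only the gather/scatter in
// C++ keeps this fast without hand-rolled matrix code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int stride) {
  return (n + stride - 1) / stride; // ceil(n / stride), pad = 1, kernel 3
}

// Gather 3x3x3 neighbourhoods (zero padding) into a matrix of shape
// [ox*oy*oz, 27*C].  Column order: kernel offset fastest (kx, ky, kz),
// then input channel.
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = out_dim(nx, stride), oy = out_dim(ny, stride),
            oz = out_dim(nz, stride);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericMatrix col(nout, 27 * C);
  const double *px = x.begin();
  double *pc = col.begin();
  const R_xlen_t plane = (R_xlen_t)nx * ny, vol = plane * nz;

  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * vol;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int k = (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          double *dst = pc + ((R_xlen_t)(k + 27 * c)) * nout;
          R_xlen_t o = 0;
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride + kz;
            const bool okz = iz >= 0 && iz < nz;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky;
              const bool oky = okz && iy >= 0 && iy < ny;
              if (!oky) {
                for (int xg = 0; xg < ox; ++xg) dst[o++] = 0.0;
              } else {
                const double *row = xc + (R_xlen_t)iz * plane + (R_xlen_t)iy * nx;
                for (int xg = 0; xg < ox; ++xg) {
                  const int ix = xg * stride + kx;
                  dst[o++] = (ix >= 0 && ix < nx) ? row[ix] : 0.0;
                }
              }
            }
          }
        }
  }
  return col;
}

// Scatter-add: exact adjoint of cpp_im2col3.  col has shape
// [ox*oy*oz, 27*C]; result is an (nx, ny, nz, C) array.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_col2im3(NumericMatrix col, IntegerVector dims, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = out_dim(nx, stride), oy = out_dim(ny, stride),
            oz = out_dim(nz, stride);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  if (col.nrow() != nout || col.ncol() != 27 * C)
    stop("col2im: column matrix shape does not match target dims");
  NumericVector x((R_xlen_t)nx * ny * nz * C);
  x.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  double *px = x.begin();
  const double *pc = col.begin();
  const R_xlen_t plane = (R_xlen_t)nx * ny, vol = plane * nz;

  for (int c = 0; c < C; ++c) {
    double *xc = px + (R_xlen_t)c * vol;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int k = (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          const double *src = pc + ((R_xlen_t)(k + 27 * c)) * nout;
          R_xlen_t o = 0;
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride + kz;
            if (iz < 0 || iz >= nz) { o += (R_xlen_t)oy * ox; continue; }
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky;
              if (iy < 0 || iy >= ny) { o += ox; continue; }
              double *row = xc + (R_xlen_t)iz * plane + (R_xlen_t)iy * nx;
              for (int xg = 0; xg < ox; ++xg) {
                const int ix = xg * stride + kx;
                if (ix >= 0 && ix < nx) row[ix] += src[o];
                ++o;
              }
            }
          }
        }
  }
  return x;
}
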