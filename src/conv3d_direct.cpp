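// Direct 3x3x3 convolution kernels (same padding, stride 1 or 2).
//
// These avoid materialising im2col matrices: each kernel tap is applied
// as a vectorised AXPY/dot over contiguous x-rows, with zero-padding
// handled by clipping the row range.  Layouts match conv3d.cpp:
// volumes are (nx, ny, nz, C) column-major arrays, weights are
// (27*Cin) x Cout with kernel offset fastest (kx, ky, kz), then channel.

#include <Rcpp.h>
using namespace Rcpp;

static inline int cdiv(int n, int s) { return (n + s - 1) / s; }

// valid output-index range [lo, hi) for input index ix = o*stride + k
static inline void orange(int n_in, int n_out, int stride, int k,
                          int &lo, int &hi) {
  lo = 0;
  while (lo < n_out && lo * stride + k < 0) ++lo;
  hi = n_out;
  while (hi > lo && (hi - 1) * stride + k >= n_in) --hi;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix W, NumericVector b, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], Ci = dims[3];
  const int ox = cdiv(nx, stride), oy = cdiv(ny, stride),
            oz = cdiv(nz, stride);
  const int Co = W.ncol();
  if (W.nrow() != 27 * Ci) stop("weight shape mismatch");
  NumericVector y((R_xlen_t)ox * oy * oz * Co);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, Co);
  const double *px = x.begin();
  double *py = y.begin();
  const R_xlen_t xpl = (R_xlen_t)nx * ny, xvol = xpl * nz;
  const R_xlen_t ypl = (R_xlen_t)ox * oy, yvol = ypl * oz;

  int xlo[3], xhi[3];
  for (int k = -1; k <= 1; ++k)
    orange(nx, ox, stride, k, xlo[k + 1], xhi[k + 1]);

  for (int co = 0; co < Co; ++co) {
    double *yc = py + (R_xlen_t)co * yvol;
    const double bco = b[co];
    for (R_xlen_t i = 0; i < yvol; ++i) yc[i] = bco;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (R_xlen_t)ci * xvol;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const double w =
              W((kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1)) + 27 * ci, co);
            if (w == 0.0) continue;
            const int lo = xlo[kx + 1], hi = xhi[kx + 1];
            for (int z = 0; z < oz; ++z) {
              const int iz = z * stride + kz;
              if (iz < 0 || iz >= nz) continue;
              for (int yy = 0; yy < oy; ++yy) {
                const int iy = yy * stride + ky;
                if (iy < 0 || iy >= ny) continue;
                const double *xrow = xc + iz * xpl + (R_xlen_t)iy * nx + kx;
                double *yrow = yc + (R_xlen_t)z * ypl + (R_xlen_t)yy * ox;
                if (stride == 1) {
                  for (int o = lo; o < hi; ++o) yrow[o] += w * xrow[o];
                } else {
                  for (int o = lo; o < hi; ++o)
                    yrow[o] += w * xrow[(R_xlen_t)o * stride];
                }
              }
            }
          }
    }
  }
  return y;
}

// gradient w.r.t. the input (also the forward pass of the stride-2
// transposed convolution): dy has the coarse dims, result the fine dims
// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv3_bwd_data(NumericVector dy, IntegerVector fine_dims,
                                 NumericMatrix W, int stride) {
  const int nx = fine_dims[0], ny = fine_dims[1], nz = fine_dims[2],
            Ci = fine_dims[3];
  const int ox = cdiv(nx, stride), oy = cdiv(ny, stride),
            oz = cdiv(nz, stride);
  const int Co = W.ncol();
  if (W.nrow() != 27 * Ci) stop("weight shape mismatch");
  NumericVector dx((R_xlen_t)nx * ny * nz * Ci);
  dx.attr("dim") = fine_dims;
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  const R_xlen_t xpl = (R_xlen_t)nx * ny, xvol = xpl * nz;
  const R_xlen_t ypl = (R_xlen_t)ox * oy, yvol = ypl * oz;

  int xlo[3], xhi[3];
  for (int k = -1; k <= 1; ++k)
    orange(nx, ox, stride, k, xlo[k + 1], xhi[k + 1]);

  for (int ci = 0; ci < Ci; ++ci) {
    double *xc = pdx + (R_xlen_t)ci * xvol;
    for (int co = 0; co < Co; ++co) {
      const double *yc = pdy + (R_xlen_t)co * yvol;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const double w =
              W((kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1)) + 27 * ci, co);
            if (w == 0.0) continue;
            const int lo = xlo[kx + 1], hi = xhi[kx + 1];
            for (int z = 0; z < oz; ++z) {
              const int iz = z * stride + kz;
              if (iz < 0 || iz >= nz) continue;
              for (int yy = 0; yy < oy; ++yy) {
                const int iy = yy * stride + ky;
                if (iy < 0 || iy >= ny) continue;
                double *xrow = xc + iz * xpl + (R_xlen_t)iy * nx + kx;
                const double *yrow = yc + (R_xlen_t)z * ypl +
                  (R_xlen_t)yy * ox;
                if (stride == 1) {
                  for (int o = lo; o < hi; ++o) xrow[o] += w * yrow[o];
                } else {
                  for (int o = lo; o < hi; ++o)
                    xrow[(R_xlen_t)o * stride] += w * yrow[o];
                }
              }
            }
          }
    }
  }
  return dx;
}

// gradient w.r.t. the weights (and bias as an attribute)
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_conv3_bwd_w(NumericVector x, IntegerVector dims,
                              NumericVector dy, int Co, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], Ci = dims[3];
  const int ox = cdiv(nx, stride), oy = cdiv(ny, stride),
            oz = cdiv(nz, stride);
  NumericMatrix dW(27 * Ci, Co);
  NumericVector db(Co);
  const double *px = x.begin();
  const double *pdy = dy.begin();
  const R_xlen_t xpl = (R_xlen_t)nx * ny, xvol = xpl * nz;
  const R_xlen_t ypl = (R_xlen_t)ox * oy, yvol = ypl * oz;

  int xlo[3], xhi[3];
  for (int k = -1; k <= 1; ++k)
    orange(nx, ox, stride, k, xlo[k + 1], xhi[k + 1]);

  for (int co = 0; co < Co; ++co) {
    const double *yc = pdy + (R_xlen_t)co * yvol;
    double bs = 0.0;
    for (R_xlen_t i = 0; i < yvol; ++i) bs += yc[i];
    db[co] = bs;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (R_xlen_t)ci * xvol;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int lo = xlo[kx + 1], hi = xhi[kx + 1];
            double acc = 0.0;
            for (int z = 0; z < oz; ++z) {
              const int iz = z * stride + kz;
              if (iz < 0 || iz >= nz) continue;
              for (int yy = 0; yy < oy; ++yy) {
                const int iy = yy * stride + ky;
                if (iy < 0 || iy >= ny) continue;
                const double *xrow = xc + iz * xpl + (R_xlen_t)iy * nx + kx;
                const double *yrow = yc + (R_xlen_t)z * ypl +
                  (R_xlen_t)yy * ox;
                if (stride == 1) {
                  for (int o = lo; o < hi; ++o) acc += yrow[o] * xrow[o];
                } else {
                  for (int o = lo; o < hi; ++o)
                    acc += yrow[o] * xrow[(R_xlen_t)o * stride];
                }
              }
            }
            dW((kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1)) + 27 * ci, co) = acc;
          }
    }
  }
  dW.attr("db") = db;
  return dW;
}
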