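// Parallel-beam in-plane system matrix for PET forward projection.
//
// Lines are parameterised by a radial offset s along (cos a, sin a) and a
// position t along the perpendicular direction; the image is sampled at a
// fixed step along each line with bilinear interpolation, so each sample
// contributes (step * weight) mm of intersection length to up to four
// pixels.  The matrix is returned as triplets and assembled into a
// dgCMatrix on the R side; its transpose is the exact adjoint.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
List cpp_projector_triplets(int nx, int ny, double dx, double dy,
                            int nbins, int nang, double step) {
  const double fovx = nx * dx, fovy = ny * dy;
  const double diag = std::sqrt(fovx * fovx + fovy * fovy);
  const double bin_w = diag / nbins;
  const double t_half = diag / 2.0;
  const int nsamp = (int)std::ceil(diag / step);

  std::vector<int> ri, ci;
  std::vector<double> vv;
  ri.reserve((size_t)nbins * nang * nsamp / 2);
  ci.reserve(ri.capacity());
  vv.reserve(ri.capacity());

  std::vector<double> acc((size_t)nx * ny, 0.0);
  std::vector<int> touched;
  touched.reserve(4 * nsamp);

  for (int a = 0; a < nang; ++a) {
    const double th = M_PI * a / nang;
    const double cth = std::cos(th), sth = std::sin(th);
    for (int b = 0; b < nbins; ++b) {
      const double s = (b - (nbins - 1) / 2.0) * bin_w;
      const int row = b + nbins * a;
      // line: p(t) = s*(cth, sth) + t*(-sth, cth)
      for (int m = 0; m < nsamp; ++m) {
        const double t = -t_half + (m + 0.5) * step;
        const double pxm = s * cth - t * sth;
        const double pym = s * sth + t * cth;
        // continuous pixel coords; pixel centres at (i - (n-1)/2) * d
        const double u = pxm / dx + (nx - 1) / 2.0;
        const double v = pym / dy + (ny - 1) / 2.0;
        const int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
        const double fu = u - i0, fv = v - j0;
        const double w[4] = { (1 - fu) * (1 - fv), fu * (1 - fv),
                              (1 - fu) * fv,       fu * fv };
        const int ii[4] = { i0, i0 + 1, i0,     i0 + 1 };
        const int jj[4] = { j0, j0,     j0 + 1, j0 + 1 };
        for (int q = 0; q < 4; ++q) {
          if (ii[q] < 0 || ii[q] >= nx || jj[q] < 0 || jj[q] >= ny) continue;
          const size_t pix = (size_t)ii[q] + (size_t)nx * jj[q];
          if (acc[pix] == 0.0) touched.push_back((int)pix);
          acc[pix] += w[q] * step;
        }
      }
      for (size_t q = 0; q < touched.size(); ++q) {
        const int pix = touched[q];
        if (acc[pix] > 0.0) {
          ri.push_back(row);
          ci.push_back(pix);
          vv.push_back(acc[pix]);
          acc[pix] = 0.0;
        }
      }
      touched.clear();
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(vv), _["bin_width"] = bin_w,
                      _["nrow"] = nbins * nang,
                      _["ncol"] = nx * ny);
}
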