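#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur, sigma in voxel units (reconstruction-kernel /
// anti-aliasing point-spread function of the simulated scanner).
// Borders are renormalised (kernel truncated at the volume edge).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(ntot), b(ntot);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < ntot; ++i) a[i] = v[i];
  if (sigma > 0) {
    int rad = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * rad + 1);
    for (int k = -rad; k <= rad; ++k)
      w[k + rad] = std::exp(-0.5 * k * k / (sigma * sigma));
    const int n[3] = {nx, ny, nz};
    const R_xlen_t s[3] = {1, nx, (R_xlen_t)nx * ny};
    for (int ax = 0; ax < 3; ++ax) {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int c[3] = {i, j, k};
            R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            double acc = 0, wsum = 0;
            int lo = std::max(-rad, -c[ax]);
            int hi = std::min(rad, n[ax] - 1 - c[ax]);
            for (int o = lo; o <= hi; ++o) {
              double wk = w[o + rad];
              acc += wk * a[id + (R_xlen_t)o * s[ax]];
              wsum += wk;
            }
            b[id] = acc / wsum;
          }
      a.swap(b);
    }
  }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = a[i];
  out.attr("dim") = dim;
  return out;
}
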