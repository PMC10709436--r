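#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel index coordinates.
// Points needing neighbours outside the grid are flagged invalid (no
// extrapolation, no clamping): the correlation metric excludes them.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dim, NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector valid(n);
  const double *v = REAL(vol);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (int k = 0; k < n; ++k) {
    double x = pts(k, 0), y = pts(k, 1), z = pts(k, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[k] = NA_REAL;
      valid[k] = false;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    R_xlen_t base = i0 * sx + j0 * sy + k0 * sz;
    double c000 = v[base],           c100 = v[base + sx];
    double c010 = v[base + sy],      c110 = v[base + sx + sy];
    double c001 = v[base + sz],      c101 = v[base + sx + sz];
    double c011 = v[base + sy + sz], c111 = v[base + sx + sy + sz];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[k] = c0 * (1 - fz) + c1 * fz;
    valid[k] = true;
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}
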