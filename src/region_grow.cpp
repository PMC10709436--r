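#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected flood fill of a supra-threshold mask from a seed voxel.
// seed is a 1-based (i, j, k) triple.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector mask, IntegerVector dim,
                             IntegerVector seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const int *m = LOGICAL(mask);
  LogicalVector out(ntot);
  int *o = LOGICAL(out);
  std::fill(o, o + ntot, 0);

  const int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
    stop("seed voxel outside the volume");
  R_xlen_t s = si + (R_xlen_t)nx * (sj + (R_xlen_t)ny * sk);
  if (!m[s]) stop("seed voxel is below threshold");

  std::vector<R_xlen_t> stack;
  stack.reserve(1 << 16);
  stack.push_back(s);
  o[s] = 1;
  while (!stack.empty()) {
    R_xlen_t cur = stack.back();
    stack.pop_back();
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    int rem = (int)(cur - (R_xlen_t)k * nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int dk = -1; dk <= 1; ++dk) {
      int zk = k + dk;
      if (zk < 0 || zk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int yj = j + dj;
        if (yj < 0 || yj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int xi = i + di;
          if (xi < 0 || xi >= nx) continue;
          R_xlen_t idx = xi + (R_xlen_t)nx * (yj + (R_xlen_t)ny * zk);
          if (m[idx] && !o[idx]) {
            o[idx] = 1;
            stack.push_back(idx);
          }
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
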