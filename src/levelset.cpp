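#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-pass chamfer distance (26-neighbourhood, weights 1 / sqrt2 / sqrt3,
// voxel units) to the set where `inside` is true.
static void chamfer(std::vector<double> &d, const int *inside,
                    int nx, int ny, int nz) {
  const double INF = 1e30;
  const double w[3] = {1.0, 1.4142135623730951, 1.7320508075688772};
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t i = 0; i < ntot; ++i) d[i] = inside[i] ? 0.0 : INF;
  auto idx = [&](int i, int j, int k) {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double cur = d[idx(i, j, k)];
        if (cur == 0.0) continue;
        for (int dk = -1; dk <= 0; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0) continue;
              int nd = std::abs(di) + std::abs(dj) + std::abs(dk);
              double cand = d[idx(ii, jj, kk)] + w[nd - 1];
              if (cand < cur) cur = cand;
            }
        d[idx(i, j, k)] = cur;
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        double cur = d[idx(i, j, k)];
        if (cur == 0.0) continue;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj < 0 || (dj == 0 && di <= 0))) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii >= nx || ii < 0 || jj < 0 || jj >= ny || kk >= nz) continue;
              int nd = std::abs(di) + std::abs(dj) + std::abs(dk);
              double cand = d[idx(ii, jj, kk)] + w[nd - 1];
              if (cand < cur) cur = cand;
            }
        d[idx(i, j, k)] = cur;
      }
}

// Approximate signed distance to the mask boundary, negative inside.
// [[Rcpp::export]]
NumericVector cpp_signed_distance(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const int *m = LOGICAL(mask);
  std::vector<int> inv(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) inv[i] = !m[i];
  std::vector<double> din(ntot), dout(ntot);
  chamfer(dout, m, nx, ny, nz);   // distance to object (0 inside)
  chamfer(din, inv.data(), nx, ny, nz); // distance to background (0 outside)
  NumericVector phi(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    phi[i] = m[i] ? -(din[i] - 0.5) : (dout[i] - 0.5);
  phi.attr("dim") = dim;
  return phi;
}

// In-place separable 3-tap binomial smoothing (1/4, 1/2, 1/4), `passes` times.
static void binomial_smooth(std::vector<double> &f, int nx, int ny, int nz,
                            int passes) {
  auto idx = [&](int i, int j, int k) {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  std::vector<double> tmp(f.size());
  for (int p = 0; p < passes; ++p) {
    for (int ax = 0; ax < 3; ++ax) {
      int s[3] = {1, nx, nx * ny};
      int n[3] = {nx, ny, nz};
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int c[3] = {i, j, k};
            R_xlen_t id = idx(i, j, k);
            double lo = (c[ax] > 0) ? f[id - s[ax]] : f[id];
            double hi = (c[ax] < n[ax] - 1) ? f[id + s[ax]] : f[id];
            tmp[id] = 0.25 * lo + 0.5 * f[id] + 0.25 * hi;
          }
      f.swap(tmp);
    }
  }
}

// Laplacian level-set refinement: the front is advected by the (smoothed)
// image Laplacian so that it settles on second-derivative zero crossings
// (edges), with mean-curvature regularisation. phi < 0 is inside.
// [[Rcpp::export]]
NumericVector cpp_levelset_evolve(NumericVector image, LogicalVector mask,
                                  IntegerVector dim, int iterations,
                                  double curvature_weight,
                                  double propagation_weight,
                                  int smoothing_passes, double dt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  auto idx = [&](int i, int j, int k) {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };

  // smoothed image -> Laplacian speed field, normalised to [-1, 1]
  std::vector<double> img(ntot);
  const double *ip = REAL(image);
  for (R_xlen_t i = 0; i < ntot; ++i) img[i] = ip[i];
  if (smoothing_passes > 0) binomial_smooth(img, nx, ny, nz, smoothing_passes);
  std::vector<double> lap(ntot, 0.0);
  double lmax = 0.0;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        R_xlen_t id = idx(i, j, k);
        double l = img[idx(i - 1, j, k)] + img[idx(i + 1, j, k)] +
                   img[idx(i, j - 1, k)] + img[idx(i, j + 1, k)] +
                   img[idx(i, j, k - 1)] + img[idx(i, j, k + 1)] -
                   6.0 * img[id];
        lap[id] = l;
        double a = std::fabs(l);
        if (a > lmax) lmax = a;
      }
  if (lmax > 0) for (R_xlen_t i = 0; i < ntot; ++i) lap[i] /= lmax;

  NumericVector phi0 = cpp_signed_distance(mask, dim);
  std::vector<double> phi(ntot), nphi(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) phi[i] = phi0[i];

  const double eps = 1e-9;
  for (int it = 0; it < iterations; ++it) {
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          R_xlen_t id = idx(i, j, k);
          // narrow band: only evolve near the front
          if (std::fabs(phi[id]) > 3.0) { nphi[id] = phi[id]; continue; }
          double px = 0.5 * (phi[idx(i + 1, j, k)] - phi[idx(i - 1, j, k)]);
          double py = 0.5 * (phi[idx(i, j + 1, k)] - phi[idx(i, j - 1, k)]);
          double pz = 0.5 * (phi[idx(i, j, k + 1)] - phi[idx(i, j, k - 1)]);
          double g2 = px * px + py * py + pz * pz;
          double g = std::sqrt(g2);
          double kappa = 0.0;
          if (g > eps) {
            double pxx = phi[idx(i + 1, j, k)] - 2 * phi[id] + phi[idx(i - 1, j, k)];
            double pyy = phi[idx(i, j + 1, k)] - 2 * phi[id] + phi[idx(i, j - 1, k)];
            double pzz = phi[idx(i, j, k + 1)] - 2 * phi[id] + phi[idx(i, j, k - 1)];
            double pxy = 0.25 * (phi[idx(i + 1, j + 1, k)] - phi[idx(i - 1, j + 1, k)] -
                                 phi[idx(i + 1, j - 1, k)] + phi[idx(i - 1, j - 1, k)]);
            double pxz = 0.25 * (phi[idx(i + 1, j, k + 1)] - phi[idx(i - 1, j, k + 1)] -
                                 phi[idx(i + 1, j, k - 1)] + phi[idx(i - 1, j, k - 1)]);
            double pyz = 0.25 * (phi[idx(i, j + 1, k + 1)] - phi[idx(i, j - 1, k + 1)] -
                                 phi[idx(i, j + 1, k - 1)] + phi[idx(i, j - 1, k - 1)]);
            kappa = (pxx * (py * py + pz * pz) + pyy * (px * px + pz * pz) +
                     pzz * (px * px + py * py) -
                     2 * (px * py * pxy + px * pz * pxz + py * pz * pyz)) /
                    (g2 * g + eps);
            if (kappa > 1.0) kappa = 1.0;
            if (kappa < -1.0) kappa = -1.0;
          }
          nphi[id] = phi[id] + dt * g * (propagation_weight * lap[id] +
                                         curvature_weight * kappa);
        }
    // faces stay fixed (object assumed interior)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 || k == nz - 1)
            nphi[idx(i, j, k)] = phi[idx(i, j, k)];
    phi.swap(nphi);
  }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = phi[i];
  out.attr("dim") = dim;
  return out;
}
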