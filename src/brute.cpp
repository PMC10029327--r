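#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brute-force maximal-inscribed-ball thickness oracle. Entirely
// self-contained: its own O(F*B) distance scan and O(F^2) candidate scan,
// no shared code with the accelerated path. Intended for grids up to ~64^3.

// [[Rcpp::export]]
NumericVector cpp_thickness_brute(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n > 300000)
    stop("grid too large for the brute-force oracle; use local_thickness()");

  std::vector<int> fx, fy, fz;
  std::vector<int> bx, by, bz;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (fg[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)]) {
          fx.push_back(i); fy.push_back(j); fz.push_back(k);
        } else {
          bx.push_back(i); by.push_back(j); bz.push_back(k);
        }
      }
  const size_t F = fx.size(), B = bx.size();
  if (F == 0) stop("empty foreground");

  // distance-to-background at every foreground voxel, by exhaustive scan
  std::vector<double> rad(F);  // inscribed-ball radius = dist to background
  for (size_t a = 0; a < F; a++) {
    double best = 1e30;
    for (size_t b = 0; b < B; b++) {
      const double dx = fx[a] - bx[b], dy = fy[a] - by[b], dz = fz[a] - bz[b];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    rad[a] = (B == 0) ? 1e15 : std::sqrt(best);
  }

  NumericVector th(n);
  for (size_t a = 0; a < F; a++) {
    double best = 0.0;
    for (size_t c = 0; c < F; c++) {
      const double r = rad[c];
      if (2.0 * r <= best) continue;
      const double dx = fx[a] - fx[c], dy = fy[a] - fy[c], dz = fz[a] - fz[c];
      if (std::sqrt(dx * dx + dy * dy + dz * dz) <= r) best = 2.0 * r;
    }
    th[fx[a] + (R_xlen_t)nx * (fy[a] + (R_xlen_t)ny * fz[a])] = best;
  }
  return th;
}
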