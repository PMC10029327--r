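#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fast model-independent local thickness: the thickness of a foreground
// voxel v is 2*max{ r(c) : |v - c| <= r(c) }, where r(c) = sqrt(dtsq(c))
// is the inscribed-ball radius at candidate center c and dtsq is the exact
// squared Euclidean distance (voxel units) to the nearest background voxel.
//
// Strategy: process candidate centers by decreasing radius, painting each
// center's digital ball with its diameter unless the ball is provably
// contained in an already painted ball. Containment is certified with an
// exact integer test: ball(c,r) subset ball(cb,rb) if rb - |c-cb| >= r,
// i.e. sqrt(A) >= sqrt(B) + sqrt(R) with A,B,R integers (squared radii /
// squared distance), checked as (A-B-R) >= 0 && (A-B-R)^2 >= 4*B*R.
// Skipping is only an optimization: any voxel the skipped ball would have
// painted already carries a value >= its diameter, so the result is
// voxel-exact with respect to the definition above.

// [[Rcpp::export]]
NumericVector cpp_thickness_fast(LogicalVector fg, NumericVector dtsq,
                                 IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<R_xlen_t> centers;
  centers.reserve(1024);
  for (R_xlen_t i = 0; i < n; i++) if (fg[i]) centers.push_back(i);
  if (centers.empty()) stop("empty foreground");

  std::sort(centers.begin(), centers.end(),
            [&](R_xlen_t a, R_xlen_t b) {
              if (dtsq[a] != dtsq[b]) return dtsq[a] > dtsq[b];
              return a < b;  // deterministic tie-break
            });

  NumericVector th(n);
  // best covering candidate per voxel: squared radius A and squared
  // center distance B of the ball with maximal depth reaching the voxel
  std::vector<double> bestA(n, -1.0), bestB(n, 0.0), bestDepth(n, -1e30);

  for (R_xlen_t cidx : centers) {
    const double R = dtsq[cidx];
    if (R <= 0) continue;
    const double sqR = std::sqrt(R);
    const double r = sqR;
    // exact containment check against the recorded candidate ball
    const double A = bestA[cidx];
    if (A > 0) {
      const double B = bestB[cidx];
      const double t = A - B - R;
      if (t >= 0 && t * t >= 4.0 * B * R) continue;  // provably covered
    }
    const int cx = (int)(cidx % nx);
    const int cy = (int)((cidx / nx) % ny);
    const int cz = (int)(cidx / sz);
    const int rr = (int)std::floor(r);
    const double Bmaxd = R;  // |u|^2 <= R, exact in integers
    const double diam = 2.0 * r;
    for (int dz = -rr; dz <= rr; dz++) {
      int z = cz + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -rr; dy <= rr; dy++) {
        int y = cy + dy; if (y < 0 || y >= ny) continue;
        const double b2yz = (double)dz * dz + (double)dy * dy;
        if (b2yz > Bmaxd) continue;
        const R_xlen_t rowbase = sy * y + sz * z;
        for (int dx = -rr; dx <= rr; dx++) {
          int x = cx + dx; if (x < 0 || x >= nx) continue;
          const double b2 = b2yz + (double)dx * dx;
          if (b2 > Bmaxd) continue;
          const R_xlen_t v = x + rowbase;
          if (!fg[v]) continue;  // thickness is defined on the foreground
          if (th[v] < diam) th[v] = diam;
          const double depth = r - std::sqrt(b2);
          if (depth > bestDepth[v]) {
            bestDepth[v] = depth; bestA[v] = R; bestB[v] = b2;
          }
        }
      }
    }
  }
  return th;
}
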