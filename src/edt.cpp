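#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope passes along each axis. Distances are between
// voxel centers, in voxel units. Sources are the TRUE voxels of `mask`.

static const double INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest index)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = D[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; i++) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = D[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; j++) D[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; k++) f[k] = D[base + sz * k];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; k++) D[base + sz * k] = d[k];
    }
  return D;
}

// Separable Gaussian smoothing with replicate edge handling, truncated
// at 3.5 sigma. Used to regularize distance fields before meshing.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector x, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(x);
  int half = (int)std::ceil(3.5 * sigma);
  std::vector<double> ker(2 * half + 1);
  double s = 0;
  for (int t = -half; t <= half; t++) {
    ker[t + half] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + half];
  }
  for (double& w : ker) w /= s;

  NumericVector a = clone(x), b(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double acc = 0;
        for (int t = -half; t <= half; t++) {
          int ii = i + t; if (ii < 0) ii = 0; if (ii >= nx) ii = nx - 1;
          acc += ker[t + half] * a[ii + sy * j + sz * k];
        }
        b[i + sy * j + sz * k] = acc;
      }
  // along y
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double acc = 0;
        for (int t = -half; t <= half; t++) {
          int jj = j + t; if (jj < 0) jj = 0; if (jj >= ny) jj = ny - 1;
          acc += ker[t + half] * b[i + sy * jj + sz * k];
        }
        a[i + sy * j + sz * k] = acc;
      }
  // along z
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double acc = 0;
        for (int t = -half; t <= half; t++) {
          int kk = k + t; if (kk < 0) kk = 0; if (kk >= nz) kk = nz - 1;
          acc += ker[t + half] * a[i + sy * j + sz * kk];
        }
        b[i + sy * j + sz * k] = acc;
      }
  return b;
}
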