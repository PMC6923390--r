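#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm), separable over axes with per-axis physical
// spacing. Input: 0 at feature voxels, BIG elsewhere, where BIG exceeds any
// achievable squared distance in the grid, so the classic finite-arithmetic
// recursion stays exact whenever at least one feature voxel exists.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w, double big) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  const double zinf = 1e300; // sentinel beyond any envelope crossing
  (void)big;
  int k = 0;
  v[0] = 0;
  z[0] = -zinf;
  z[1] = zinf;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = zinf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  const double big = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : big;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  for (int z = 0; z < nz; ++z)          // pass along x
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[x + nx * (y + ny * z)];
      dt1d(f, d, nx, spacing[0], big);
      for (int x = 0; x < nx; ++x) out[x + nx * (y + ny * z)] = d[x];
    }
  for (int z = 0; z < nz; ++z)          // pass along y
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[x + nx * (y + ny * z)];
      dt1d(f, d, ny, spacing[1], big);
      for (int y = 0; y < ny; ++y) out[x + nx * (y + ny * z)] = d[y];
    }
  for (int y = 0; y < ny; ++y)          // pass along z
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[x + nx * (y + ny * z)];
      dt1d(f, d, nz, spacing[2], big);
      for (int z = 0; z < nz; ++z) out[x + nx * (y + ny * z)] = d[z];
    }
  return out;
}
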