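#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect an out-of-range index back into [0, n-1] (mirror boundary).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Normalized Gaussian kernel truncated at 3.5 sigma. Must stay in sync with
// .gauss_kernel() on the R side (used to compute the delta-peak factor).
static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t j = 0; j < k.size(); ++j) k[j] /= s;
  return k;
}

// Separable Gaussian blur of a 3D volume stored column-major with
// dims = (nz, ny, nx); sigmas (voxels) per axis in the same order.
// A zero sigma skips that axis.
// [[Rcpp::export]]
NumericVector blur3d_cpp(NumericVector vol, IntegerVector dims, NumericVector sigmas) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume length does not match dims");
  std::vector<double> cur(vol.begin(), vol.end()), tmp(n);

  const int strides[3] = {1, nz, nz * ny};
  const int sizes[3] = {nz, ny, nx};

  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigmas[ax];
    if (sg <= 0) continue;
    std::vector<double> k = gauss_kernel(sg);
    int r = ((int)k.size() - 1) / 2;
    int na = sizes[ax];
    int sa = strides[ax];
    // iterate over all lines along axis ax
    int nb = sizes[(ax + 1) % 3], nc = sizes[(ax + 2) % 3];
    int sb = strides[(ax + 1) % 3], sc = strides[(ax + 2) % 3];
    for (int c = 0; c < nc; ++c) {
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = (R_xlen_t)b * sb + (R_xlen_t)c * sc;
        for (int a = 0; a < na; ++a) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ai = reflect(a + t, na);
            acc += k[t + r] * cur[base + (R_xlen_t)ai * sa];
          }
          tmp[base + (R_xlen_t)a * sa] = acc;
        }
      }
    }
    cur.swap(tmp);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
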