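#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical volume (column-major,
// dims = (nz, ny, nx)) with 6/18/26 connectivity. Labels are assigned in
// raster order of each component's first voxel, so output is deterministic.
// A 2D slice (nz = 1) reduces to 4-connectivity (conn = 6) or
// 8-connectivity (conn = 18 or 26).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dzs, dys, dxs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }
  const int nb = (int)dzs.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int j = 0; j < nb; ++j) {
        int zz = z + dzs[j], yy = y + dys[j], xx = x + dxs[j];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
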