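#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first search.
// mask: logical vector in R array (column-major) order with dims d = (nz, ny, nx).
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighborhood).
// Returns an integer array of provisional labels (1..n in scan order of the
// first voxel reached); 0 = background. Deterministic for a fixed mask.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nb = (int)dz.size();

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int current = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nb; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t u = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[u] && labels[u] == 0) {
          labels[u] = current;
          q.push(u);
        }
      }
    }
  }
  return labels;
}
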