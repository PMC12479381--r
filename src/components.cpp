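#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label 26-connected components of a binary 3D array. Returns an integer
// array of the same shape with labels 1..K (0 = background), in first-found
// order (deterministic for a given input).
// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(NumericVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cz = cur / ((R_xlen_t)nx * ny);
      int rem = cur - (R_xlen_t)cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int z = cz + dz;
        if (z < 0 || z >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y = cy + dy;
          if (y < 0 || y >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x = cx + dx;
            if (x < 0 || x >= nx) continue;
            R_xlen_t nb = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
            if (mask[nb] != 0 && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return lab;
}
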