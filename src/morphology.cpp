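#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labelling of a logical volume, 26-connectivity.
// Returns an integer volume: 0 = background, 1..n = component id.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int comp = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++comp;
    lab[s] = comp;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && !lab[w]) {
              lab[w] = comp;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = comp;
  return lab;
}

// Fill fully enclosed cavities slice by slice: within each z-slice, flood the
// background with 4-connectivity from the slice border; background pixels the
// flood cannot reach are enclosed holes and become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_slices(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(clone(mask));
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    const R_xlen_t off = (R_xlen_t)z * nx * ny;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        if (x == 0 || y == 0 || x == nx - 1 || y == ny - 1) {
          int p = x + nx * y;
          if (!mask[off + p] && !reach[p]) {
            reach[p] = 1;
            stack.push_back(p);
          }
        }
      }
    }
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int x = p % nx, y = p / nx;
      const int nbr[4][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1}};
      for (int k = 0; k < 4; ++k) {
        int xx = x + nbr[k][0], yy = y + nbr[k][1];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
        int q = xx + nx * yy;
        if (!mask[off + q] && !reach[q]) {
          reach[q] = 1;
          stack.push_back(q);
        }
      }
    }
    for (int p = 0; p < nx * ny; ++p)
      if (!mask[off + p] && !reach[p]) out[off + p] = true;
  }
  out.attr("dim") = dims;
  return out;
}
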