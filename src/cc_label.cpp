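#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary 2D/3D grid.
// connectivity: 2D masks accept 4 or 8; 3D masks accept 6, 18 or 26.
// Labels are assigned in order of the first (smallest linear index) voxel
// of each component, which fixes the documented tie-break for
// equally-sized components.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 2 && dim.size() != 3)
    stop("mask must be 2D or 3D");
  const int nx = dim[0];
  const int ny = dim[1];
  const int nz = (dim.size() == 3) ? dim[2] : 1;
  const bool is3d = dim.size() == 3;
  if (is3d) {
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
      stop("3D connectivity must be 6, 18 or 26");
  } else {
    if (connectivity != 4 && connectivity != 8)
      stop("2D connectivity must be 4 or 8");
  }
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz) {
    if (!is3d && dz != 0) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        bool keep;
        if (is3d) {
          keep = (connectivity == 26) ? true
               : (connectivity == 18) ? (manh <= 2)
                                      : (manh == 1);
        } else {
          keep = (connectivity == 8) ? true : (manh == 1);
        }
        if (keep) { ox.push_back(dx); oy.push_back(dy); oz.push_back(dz); }
      }
    }
  }
  const int noff = (int)ox.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  const R_xlen_t plane = (R_xlen_t)nx * ny;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cz = (int)(cur / plane);
      R_xlen_t rem = cur - (R_xlen_t)cz * plane;
      int cy = (int)(rem / nx);
      int cx = (int)(rem - (R_xlen_t)cy * nx);
      for (int k = 0; k < noff; ++k) {
        int px = cx + ox[k], py = cy + oy[k], pz = cz + oz[k];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)pz * plane + (R_xlen_t)py * nx + px;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  labels.attr("n_components") = next_label;
  return labels;
}
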