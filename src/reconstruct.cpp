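#include <Rcpp.h>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (8-connectivity):
// alternating forward/backward raster sweeps until stable. Equivalent to
// iterating elementary geodesic dilations of `marker` under `mask` to
// convergence.
// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericMatrix reconstruct_cpp(NumericMatrix marker, NumericMatrix mask,
                              int max_sweeps = 1000) {
  const int H = marker.nrow(), W = marker.ncol();
  NumericMatrix cur(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      cur(i, j) = std::min(marker(i, j), mask(i, j));
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    // forward: top-left to bottom-right
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double v = cur(i, j);
        if (i > 0) v = std::max(v, cur(i - 1, j));
        if (j > 0) {
          v = std::max(v, cur(i, j - 1));
          if (i > 0) v = std::max(v, cur(i - 1, j - 1));
          if (i < H - 1) v = std::max(v, cur(i + 1, j - 1));
        }
        v = std::min(v, mask(i, j));
        if (v > cur(i, j)) { cur(i, j) = v; changed = true; }
      }
    }
    // backward: bottom-right to top-left
    for (int j = W - 1; j >= 0; --j) {
      for (int i = H - 1; i >= 0; --i) {
        double v = cur(i, j);
        if (i < H - 1) v = std::max(v, cur(i + 1, j));
        if (j < W - 1) {
          v = std::max(v, cur(i, j + 1));
          if (i < H - 1) v = std::max(v, cur(i + 1, j + 1));
          if (i > 0) v = std::max(v, cur(i - 1, j + 1));
        }
        v = std::min(v, mask(i, j));
        if (v > cur(i, j)) { cur(i, j) = v; changed = true; }
      }
    }
    if (!changed) break;
  }
  return cur;
}
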