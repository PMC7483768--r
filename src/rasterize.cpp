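// Polygon rasterization with an explicit pixel-center convention:
// coordinates are 0-based (row, col), pixel centers sit at integer positions,
// a pixel belongs to a polygon when its center is strictly inside (even-odd
// rule) or lies on the boundary.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline bool on_segment(double py, double px, double ay, double ax,
                              double by, double bx) {
  const double eps = 1e-9;
  double cross = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
  if (std::fabs(cross) > eps * (1.0 + std::fabs(bx - ax) + std::fabs(by - ay)))
    return false;
  double dot = (px - ax) * (bx - ax) + (py - ay) * (by - ay);
  double len2 = (bx - ax) * (bx - ax) + (by - ay) * (by - ay);
  return dot >= -eps && dot <= len2 + eps;
}

static bool point_in_polygon(double py, double px, const arma::mat& v) {
  // v: n x 2 matrix of (row, col) vertices
  int n = v.n_rows;
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double ay = v(i, 0), ax = v(i, 1);
    double by = v(j, 0), bx = v(j, 1);
    if (on_segment(py, px, ay, ax, by, bx)) return true;
    // even-odd crossing test on the horizontal ray in +x direction
    if ((ay > py) != (by > py)) {
      double xint = ax + (py - ay) / (by - ay) * (bx - ax);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// Fill polygon into an integer label map (in place semantics via return).
// label_map: H x W integer matrix; vertices: n x 2 (row, col).
// Returns the number of pixels that previously held a different non-base label
// (overlap diagnostics for the caller).
// [[Rcpp::export]]
int fill_polygon_cpp(IntegerMatrix label_map, NumericMatrix vertices,
                     int label, int base_label) {
  int H = label_map.nrow(), W = label_map.ncol();
  arma::mat v(vertices.nrow(), 2);
  for (int i = 0; i < vertices.nrow(); ++i) {
    v(i, 0) = vertices(i, 0);
    v(i, 1) = vertices(i, 1);
  }
  int r0 = std::max(0, (int)std::floor(v.col(0).min()));
  int r1 = std::min(H - 1, (int)std::ceil(v.col(0).max()));
  int c0 = std::max(0, (int)std::floor(v.col(1).min()));
  int c1 = std::min(W - 1, (int)std::ceil(v.col(1).max()));
  int overwritten = 0;
  for (int c = c0; c <= c1; ++c) {
    for (int r = r0; r <= r1; ++r) {
      if (point_in_polygon((double)r, (double)c, v)) {
        int cur = label_map(r, c);
        if (cur != base_label && cur != label) ++overwritten;
        label_map(r, c) = label;
      }
    }
  }
  return overwritten;
}

// [[Rcpp::export]]
LogicalMatrix polygon_mask_cpp(int H, int W, NumericMatrix vertices) {
  LogicalMatrix out(H, W);
  IntegerMatrix lm(H, W);
  fill_polygon_cpp(lm, vertices, 1, 0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = lm(i, j) == 1;
  return out;
}
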