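// Connected-component labelling and threshold-sweep region scoring for the
// detection analyses. 4- or 8-connectivity, selectable.
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// Label connected components of a logical matrix. Returns an integer matrix
// with 0 for background and 1..n for components (scan-order ids).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int ncomp = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  int nn = connectivity == 8 ? 8 : 4;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++ncomp;
      q.push({r, c});
      while (!q.empty()) {
        auto [cr, cc] = q.front();
        q.pop();
        for (int i = 0; i < nn; ++i) {
          int nr = cr + dr[i], nc = cc + dc[i];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = ncomp;
            q.push({nr, nc});
          }
        }
      }
    }
  return lab;
}

// Qualifying-region score of a probability map: the largest pixel value v
// such that the superlevel set {p >= v} contains a connected component of
// more than `min_pixels` pixels. The map is "predicted positive" at cut-off
// c exactly when score > c (cut-offs are strict). Returns 0 when no
// superlevel set ever qualifies.
// [[Rcpp::export]]
double region_score_cpp(NumericMatrix prob, int min_pixels, int connectivity) {
  int H = prob.nrow(), W = prob.ncol();
  int n = H * W;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double* p = prob.begin();
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return p[a] > p[b]; });
  std::vector<int> parent(n, -1), size(n, 0);
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  int nn = connectivity == 8 ? 8 : 4;
  int maxsize = 0;
  size_t i = 0;
  while (i < order.size()) {
    double v = p[order[i]];
    if (v <= 0) break;
    size_t j = i;
    // activate the whole tie group {p == v} before testing
    while (j < order.size() && p[order[j]] == v) {
      int idx = order[j];
      parent[idx] = idx;
      size[idx] = 1;
      ++j;
    }
    for (size_t t = i; t < j; ++t) {
      int idx = order[t];
      int r = idx % H, c = idx / H;
      for (int k = 0; k < nn; ++k) {
        int nr = r + dr[k], nc = c + dc[k];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        int nidx = nr + nc * H;
        if (parent[nidx] == -1) continue;
        int ra = find(idx), rb = find(nidx);
        if (ra != rb) {
          if (size[ra] < size[rb]) std::swap(ra, rb);
          parent[rb] = ra;
          size[ra] += size[rb];
          if (size[ra] > maxsize) maxsize = size[ra];
        }
      }
      if (size[find(idx)] > maxsize) maxsize = size[find(idx)];
    }
    if (maxsize > min_pixels) return v;
    i = j;
  }
  return 0.0;
}
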