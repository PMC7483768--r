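// Image-level primitives used by augmentation, pooling and the synthetic
// biopsy renderer. Images are H x W x C numeric arrays in [0,1]; label maps
// are H x W integer matrices with 1-based class indices.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Affine warp. `A` is the 2x3 inverse map taking OUTPUT pixel-center
// coordinates (row, col) to INPUT coordinates:
//   src = A[,1:2] %*% c(r, c) + A[,3]
// Image channels are sampled bilinearly with `fill` outside the canvas;
// the label map is sampled nearest-neighbour with `label_fill`.
// [[Rcpp::export]]
List affine_warp_cpp(NumericVector image, IntegerMatrix labels,
                     NumericMatrix A, NumericVector fill, int label_fill) {
  IntegerVector dims = image.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2];
  NumericVector out(image.size());
  out.attr("dim") = dims;
  IntegerMatrix lout(H, W);
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double* img = image.begin();
  double* o = out.begin();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double sr = a00 * r + a01 * c + a02;
      double sc = a10 * r + a11 * c + a12;
      int idx = r + c * H;
      // nearest neighbour for labels
      int nr = (int)std::lround(sr), nc = (int)std::lround(sc);
      lout(r, c) = (nr >= 0 && nr < H && nc >= 0 && nc < W) ? labels(nr, nc)
                                                           : label_fill;
      // bilinear for image
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        double v;
        if (r0 < -1 || r0 > H - 1 || c0 < -1 || c0 > W - 1) {
          v = fill[ch];
        } else {
          int base = ch * H * W;
          auto px = [&](int rr, int cc) -> double {
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) return fill[ch];
            return img[base + rr + cc * H];
          };
          v = (1 - fr) * (1 - fc) * px(r0, c0) + fr * (1 - fc) * px(r0 + 1, c0) +
              (1 - fr) * fc * px(r0, c0 + 1) + fr * fc * px(r0 + 1, c0 + 1);
        }
        o[ch * H * W + idx] = v;
      }
    }
  }
  return List::create(_["image"] = out, _["labels"] = lout);
}

// Block-mean pooling of an H x W matrix by integer factor f.
// [[Rcpp::export]]
NumericMatrix pool_mean_cpp(NumericMatrix x, int f) {
  int H = x.nrow(), W = x.ncol();
  int OH = H / f, OW = W / f;
  NumericMatrix out(OH, OW);
  double inv = 1.0 / (f * (double)f);
  for (int oc = 0; oc < OW; ++oc)
    for (int orr = 0; orr < OH; ++orr) {
      double s = 0;
      for (int c = oc * f; c < (oc + 1) * f; ++c)
        for (int r = orr * f; r < (orr + 1) * f; ++r) s += x(r, c);
      out(orr, oc) = s * inv;
    }
  return out;
}

// Pool a 1-based label map into per-class soft fractions: returns an
// OH x OW x K array where cell (i,j,k) is the fraction of the f x f block
// carrying label k.
// [[Rcpp::export]]
NumericVector pool_labels_cpp(IntegerMatrix labels, int f, int K) {
  int H = labels.nrow(), W = labels.ncol();
  int OH = H / f, OW = W / f;
  NumericVector out(OH * OW * K);
  out.attr("dim") = IntegerVector::create(OH, OW, K);
  double inv = 1.0 / (f * (double)f);
  for (int oc = 0; oc < OW; ++oc)
    for (int orr = 0; orr < OH; ++orr)
      for (int c = oc * f; c < (oc + 1) * f; ++c)
        for (int r = orr * f; r < (orr + 1) * f; ++r) {
          int k = labels(r, c) - 1;
          out[orr + oc * OH + k * OH * OW] += inv;
        }
  return out;
}

// Draw anti-aliased filled ellipses onto an image (in place on a copy).
// params: n x 6 matrix with columns (row, col, semi_a, semi_b, angle_rad,
// alpha); color: n x 3.
// [[Rcpp::export]]
NumericVector draw_ellipses_cpp(NumericVector image, NumericMatrix params,
                                NumericMatrix color) {
  NumericVector out = clone(image);
  IntegerVector dims = image.attr("dim");
  int H = dims[0], W = dims[1];
  double* o = out.begin();
  for (int e = 0; e < params.nrow(); ++e) {
    double cy = params(e, 0), cx = params(e, 1);
    double a = params(e, 2), b = params(e, 3), th = params(e, 4);
    double alpha = params(e, 5);
    double ct = std::cos(th), st = std::sin(th);
    double rad = std::max(a, b) + 1.5;
    int r0 = std::max(0, (int)std::floor(cy - rad));
    int r1 = std::min(H - 1, (int)std::ceil(cy + rad));
    int c0 = std::max(0, (int)std::floor(cx - rad));
    int c1 = std::min(W - 1, (int)std::ceil(cx + rad));
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        double dy = r - cy, dx = c - cx;
        double u = (dy * ct + dx * st) / a;
        double v = (-dy * st + dx * ct) / b;
        double d = std::sqrt(u * u + v * v);
        // soft edge ~1 px wide for anti-aliasing
        double cov = 1.0 - (d - 1.0) / (1.5 / std::min(a, b));
        cov = std::min(1.0, std::max(0.0, cov));
        double w = cov * alpha;
        if (w <= 0) continue;
        for (int ch = 0; ch < 3; ++ch) {
          int idx = ch * H * W + r + c * H;
          o[idx] = (1 - w) * o[idx] + w * color(e, ch);
        }
      }
  }
  return out;
}

// Assemble an augmented training batch in one pass: decode 8-bit patch
// images, apply the affine warp (bilinear image / nearest labels), the
// photometric transform, and pool the warped label map to the output grid.
// images: list of raw vectors (H*W*3, 0..255); labels: list of H x W
// integer matrices; A_list: list of 2x3 inverse affine maps;
// phot: N x 5 matrix (shift_r, shift_g, shift_b, res_min, res_max).
// [[Rcpp::export]]
List assemble_batch_cpp(List images, List labels, List A_list,
                        NumericMatrix phot, int H, int W, double fill,
                        int pool_factor, int K) {
  int N = images.size();
  int OH = H / pool_factor, OW = W / pool_factor;
  NumericVector x((R_xlen_t)H * W * 3 * N);
  x.attr("dim") = IntegerVector::create(H, W, 3, N);
  NumericVector y((R_xlen_t)OH * OW * K * N);
  y.attr("dim") = IntegerVector::create(OH, OW, K, N);
  double inv_pool = 1.0 / (pool_factor * (double)pool_factor);
  for (int n = 0; n < N; ++n) {
    RawVector img = images[n];
    IntegerMatrix lab = labels[n];
    NumericMatrix A = A_list[n];
    const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
    const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
    double sh[3] = {phot(n, 0), phot(n, 1), phot(n, 2)};
    double rmin = phot(n, 3), rspan = phot(n, 4) - phot(n, 3);
    const Rbyte* im = img.begin();
    double* xo = x.begin() + (R_xlen_t)n * H * W * 3;
    double* yo = y.begin() + (R_xlen_t)n * OH * OW * K;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double sr = a00 * r + a01 * c + a02;
        double sc = a10 * r + a11 * c + a12;
        int idx = r + c * H;
        int nr = (int)std::lround(sr), nc = (int)std::lround(sc);
        int lv = (nr >= 0 && nr < H && nc >= 0 && nc < W) ? lab(nr, nc) : 1;
        yo[(r / pool_factor) + (c / pool_factor) * OH +
           (lv - 1) * OH * OW] += inv_pool;
        int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        double fr = sr - r0, fc = sc - c0;
        bool outside = r0 < -1 || r0 > H - 1 || c0 < -1 || c0 > W - 1;
        for (int ch = 0; ch < 3; ++ch) {
          double v;
          if (outside) {
            v = fill;
          } else {
            R_xlen_t base = (R_xlen_t)ch * H * W;
            auto px = [&](int rr, int cc) -> double {
              if (rr < 0 || rr >= H || cc < 0 || cc >= W) return fill;
              return im[base + rr + cc * H] / 255.0;
            };
            v = (1 - fr) * (1 - fc) * px(r0, c0) +
                fr * (1 - fc) * px(r0 + 1, c0) +
                (1 - fr) * fc * px(r0, c0 + 1) + fr * fc * px(r0 + 1, c0 + 1);
          }
          v += sh[ch];
          if (v < 0) v = 0;
          if (v > 1) v = 1;
          xo[ch * H * W + idx] = rmin + v * rspan;
        }
      }
    }
  }
  return List::create(_["x"] = x, _["y"] = y);
}

// Separable Gaussian blur of an H x W matrix (reflective borders).
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  auto refl = [](int i, int n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
    return std::min(std::max(i, 0), n - 1);
  };
  for (int c = 0; c < W; ++c) {
    const double* xc = &x(0, c);
    double* tc = &tmp(0, c);
    for (int r = 0; r < std::min(rad, H); ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * xc[refl(r + i, H)];
      tc[r] = acc;
    }
    for (int r = rad; r < H - rad; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * xc[r + i];
      tc[r] = acc;
    }
    for (int r = std::max(H - rad, rad); r < H; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * xc[refl(r + i, H)];
      tc[r] = acc;
    }
  }
  for (int c = 0; c < W; ++c) {
    bool interior = c >= rad && c < W - rad;
    double* oc = &out(0, c);
    for (int r = 0; r < H; ++r) oc[r] = 0;
    for (int i = -rad; i <= rad; ++i) {
      int cc = interior ? c + i : refl(c + i, W);
      const double* tc = &tmp(0, cc);
      double kv = k[i + rad];
      for (int r = 0; r < H; ++r) oc[r] += kv * tc[r];
    }
  }
  return out;
}
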