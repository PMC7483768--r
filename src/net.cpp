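// Coarse-output multi-class segmentation network.
//
// Architecture: `n_blocks` convolution blocks, each holding two 3x3
// convolutions with batch normalization, a squeeze-and-excitation channel
// recalibration and an additive residual path (1x1 projection when the
// channel count changes), joined by 2x2 stride-2 convolutions followed by
// BN and ReLU. A final 1x1 convolution projects to the class channels and a
// per-pixel softmax yields probabilities; the output grid is
// 2^(n_blocks-1) times smaller than the input. Training uses SGD with
// momentum on a class-weighted soft Dice loss over block-averaged soft
// reference masks.
//
// Activations are stored as (N*H*W, C) single-precision matrices, pixel
// index p = r + c*H (column-major, matching R). Convolutions run as
// im2col + GEMM; backprop is hand-derived per layer.
#include <RcppArmadillo.h>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

namespace {

// column-wise fused helpers: activations are tall (N*H*W rows), so all
// per-channel arithmetic runs over contiguous columns
inline void add_bias(fmat& X, const fmat& b) {
  for (arma::uword j = 0; j < X.n_cols; ++j) X.col(j) += b(0, j);
}
inline void affine_cols(fmat& X, const frowvec& a, const frowvec& c) {
  for (arma::uword j = 0; j < X.n_cols; ++j) X.col(j) = X.col(j) * a(j) + c(j);
}
inline void relu_mask(fmat& X, fmat& mask, bool want_mask) {
  if (want_mask) {
    mask.set_size(X.n_rows, X.n_cols);
    float* m = mask.memptr();
    float* x = X.memptr();
    for (arma::uword i = 0; i < X.n_elem; ++i) {
      if (x[i] > 0) {
        m[i] = 1.0f;
      } else {
        m[i] = 0.0f;
        x[i] = 0.0f;
      }
    }
  } else {
    float* x = X.memptr();
    for (arma::uword i = 0; i < X.n_elem; ++i) {
      if (x[i] < 0) x[i] = 0.0f;
    }
  }
}

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {  // splitmix64: identical on every platform
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  float runif(float lo, float hi) {
    double u = (next() >> 11) * (1.0 / 9007199254740992.0);
    return lo + (float)(u * (hi - lo));
  }
};

struct Param {
  fmat W, G, V;
  void alloc(int r, int c) {
    W.zeros(r, c);
    G.zeros(r, c);
    V.zeros(r, c);
  }
};

struct Conv {
  int k = 3, stride = 1, cin = 0, cout = 0;
  Param W, b;  // W: (cin*k*k, cout); b: (1, cout)
  fmat cols;   // training cache (the 1x1 case caches the input itself)
  int Hi = 0, Wi = 0, N = 0;

  void init(int k_, int stride_, int cin_, int cout_, XRng& rng) {
    k = k_;
    stride = stride_;
    cin = cin_;
    cout = cout_;
    W.alloc(cin * k * k, cout);
    b.alloc(1, cout);
    float lim = std::sqrt(6.0f / (float)(cin * k * k + cout * k * k));
    for (arma::uword i = 0; i < W.W.n_elem; ++i) W.W(i) = rng.runif(-lim, lim);
  }
  int oh() const { return stride == 2 ? Hi / 2 : Hi; }
  int ow() const { return stride == 2 ? Wi / 2 : Wi; }

  void im2col(const fmat& X, fmat& cc) const {
    int HW = Hi * Wi;
    if (k == 3) {
      cc.zeros((arma::uword)N * HW, (arma::uword)cin * 9);
      for (int n = 0; n < N; ++n)
        for (int ch = 0; ch < cin; ++ch) {
          const float* src = X.colptr(ch) + (arma::uword)n * HW;
          for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              int oi = (dr + 1) * 3 + (dc + 1);
              float* dst = cc.colptr(ch * 9 + oi) + (arma::uword)n * HW;
              int r0 = std::max(0, -dr), r1 = Hi - 1 - std::max(0, dr);
              int c0 = std::max(0, -dc), c1 = Wi - 1 - std::max(0, dc);
              int len = r1 - r0 + 1;
              if (len <= 0) continue;
              for (int c = c0; c <= c1; ++c)
                std::memcpy(dst + r0 + c * Hi, src + (r0 + dr) + (c + dc) * Hi,
                            sizeof(float) * len);
            }
        }
    } else {  // k == 2, stride 2
      int OH = Hi / 2, OW = Wi / 2, OHW = OH * OW;
      cc.zeros((arma::uword)N * OHW, (arma::uword)cin * 4);
      for (int n = 0; n < N; ++n)
        for (int ch = 0; ch < cin; ++ch) {
          const float* src = X.colptr(ch) + (arma::uword)n * Hi * Wi;
          for (int dr = 0; dr <= 1; ++dr)
            for (int dc = 0; dc <= 1; ++dc) {
              float* dst = cc.colptr(ch * 4 + dr * 2 + dc) + (arma::uword)n * OHW;
              for (int oc = 0; oc < OW; ++oc)
                for (int orr = 0; orr < OH; ++orr)
                  dst[orr + oc * OH] = src[(2 * orr + dr) + (2 * oc + dc) * Hi];
            }
        }
    }
  }

  fmat forward(const fmat& X, int H_, int W_, int N_, bool train) {
    Hi = H_;
    Wi = W_;
    N = N_;
    fmat Y;
    if (k == 1) {
      if (train) cols = X;
      Y = X * W.W;
    } else {
      fmat local;
      fmat& cc = train ? cols : local;
      im2col(X, cc);
      Y = cc * W.W;
    }
    add_bias(Y, b.W);
    return Y;
  }

  fmat backward(const fmat& dY) {
    W.G += cols.t() * dY;
    b.G += arma::sum(dY, 0);
    fmat dX;
    if (k == 1) {
      dX = dY * W.W.t();
      return dX;
    }
    fmat dcols = dY * W.W.t();
    int HW = Hi * Wi;
    dX.zeros((arma::uword)N * HW, cin);
    if (k == 3) {
      for (int n = 0; n < N; ++n)
        for (int ch = 0; ch < cin; ++ch) {
          float* dst = dX.colptr(ch) + (arma::uword)n * HW;
          for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              int oi = (dr + 1) * 3 + (dc + 1);
              const float* src = dcols.colptr(ch * 9 + oi) + (arma::uword)n * HW;
              int r0 = std::max(0, -dr), r1 = Hi - 1 - std::max(0, dr);
              int c0 = std::max(0, -dc), c1 = Wi - 1 - std::max(0, dc);
              for (int c = c0; c <= c1; ++c) {
                float* d = dst + (r0 + dr) + (c + dc) * Hi;
                const float* s = src + r0 + c * Hi;
                for (int r = 0; r <= r1 - r0; ++r) d[r] += s[r];
              }
            }
        }
    } else {
      int OH = Hi / 2, OW = Wi / 2, OHW = OH * OW;
      for (int n = 0; n < N; ++n)
        for (int ch = 0; ch < cin; ++ch) {
          float* dst = dX.colptr(ch) + (arma::uword)n * Hi * Wi;
          for (int dr = 0; dr <= 1; ++dr)
            for (int dc = 0; dc <= 1; ++dc) {
              const float* src =
                  dcols.colptr(ch * 4 + dr * 2 + dc) + (arma::uword)n * OHW;
              for (int oc = 0; oc < OW; ++oc)
                for (int orr = 0; orr < OH; ++orr)
                  dst[(2 * orr + dr) + (2 * oc + dc) * Hi] +=
                      src[orr + oc * OH];
            }
        }
    }
    // cols buffer kept for reuse across iterations
    return dX;
  }
};

struct BN {
  Param g, bt;
  frowvec rmean, rvar;
  float mom = 0.9f, eps = 1e-5f;
  fmat xhat;
  frowvec invstd;

  void init(int C) {
    g.alloc(1, C);
    g.W.ones();
    bt.alloc(1, C);
    rmean.zeros(C);
    rvar.ones(C);
  }
  fmat forward(const fmat& X, bool train) {
    fmat Y;
    if (train) {
      frowvec m = arma::mean(X, 0);
      frowvec v = arma::mean(arma::square(X), 0) - arma::square(m);
      v.transform([](float x) { return x > 0 ? x : 0; });
      invstd = 1.0f / arma::sqrt(v + eps);
      xhat = X;
      affine_cols(xhat, invstd, -m % invstd);
      Y = xhat;
      affine_cols(Y, g.W.row(0), bt.W.row(0));
      rmean = mom * rmean + (1 - mom) * m;
      rvar = mom * rvar + (1 - mom) * v;
    } else {
      frowvec is = 1.0f / arma::sqrt(rvar + eps);
      frowvec a = is % g.W.row(0);
      Y = X;
      affine_cols(Y, a, bt.W.row(0) - rmean % a);
    }
    return Y;
  }
  fmat backward(const fmat& dY) {
    fmat dX(dY.n_rows, dY.n_cols);
    for (arma::uword j = 0; j < dY.n_cols; ++j) {
      double sg = arma::dot(dY.col(j), xhat.col(j));
      double sb = arma::accu(dY.col(j));
      g.G(0, j) += (float)sg;
      bt.G(0, j) += (float)sb;
      float gam = g.W(0, j);
      float M = (float)dY.n_rows;
      // dX = invstd * gamma * (dY - mean(dY) - xhat * mean(dY*xhat))
      float c1 = gam * (float)(sb / M);
      float c2 = gam * (float)(sg / M);
      dX.col(j) = (gam * dY.col(j) - c1 - xhat.col(j) * c2) * invstd(j);
    }
    // xhat buffer kept for reuse
    return dX;
  }
};

struct SE {
  int C = 0, Ch = 0;
  Param W1, b1, W2, b2;
  fmat Xc, z, h, s;
  int HW = 0, N = 0;

  void init(int C_, int ratio, XRng& rng) {
    C = C_;
    Ch = std::max(1, C / ratio);
    W1.alloc(C, Ch);
    b1.alloc(1, Ch);
    W2.alloc(Ch, C);
    b2.alloc(1, C);
    float l1 = std::sqrt(6.0f / (float)(C + Ch));
    for (arma::uword i = 0; i < W1.W.n_elem; ++i) W1.W(i) = rng.runif(-l1, l1);
    float l2 = std::sqrt(6.0f / (float)(Ch + C));
    for (arma::uword i = 0; i < W2.W.n_elem; ++i) W2.W(i) = rng.runif(-l2, l2);
  }
  fmat forward(const fmat& X, int HW_, int N_, bool train) {
    HW = HW_;
    N = N_;
    z.set_size(N, C);
    for (int n = 0; n < N; ++n)
      z.row(n) = arma::mean(X.rows((arma::uword)n * HW, (arma::uword)(n + 1) * HW - 1), 0);
    h = z * W1.W;
    h.each_row() += b1.W.row(0);  // small (N x C/r)
    h.transform([](float x) { return x > 0 ? x : 0; });
    s = h * W2.W;
    s.each_row() += b2.W.row(0);
    s.transform([](float x) { return 1.0f / (1.0f + std::exp(-x)); });
    if (train) Xc = X;
    fmat Y = X;
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < C; ++j)
        Y.col(j).subvec((arma::uword)n * HW, (arma::uword)(n + 1) * HW - 1) *=
            s(n, j);
    return Y;
  }
  fmat backward(const fmat& dY) {
    fmat dX = dY;
    fmat ds(N, C);
    for (int n = 0; n < N; ++n) {
      arma::uword a = (arma::uword)n * HW, bnd = (arma::uword)(n + 1) * HW - 1;
      for (int j = 0; j < C; ++j) {
        ds(n, j) = (float)arma::dot(dY.col(j).subvec(a, bnd),
                                    Xc.col(j).subvec(a, bnd));
        dX.col(j).subvec(a, bnd) *= s(n, j);
      }
    }
    fmat dp2 = ds % s % (1.0f - s);
    W2.G += h.t() * dp2;
    b2.G += arma::sum(dp2, 0);
    fmat dh = dp2 * W2.W.t();
    for (arma::uword i = 0; i < dh.n_elem; ++i) {
      if (h(i) <= 0) dh(i) = 0;
    }
    W1.G += z.t() * dh;
    b1.G += arma::sum(dh, 0);
    fmat dz = dh * W1.W.t();
    dz /= (float)HW;
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < C; ++j)
        dX.col(j).subvec((arma::uword)n * HW, (arma::uword)(n + 1) * HW - 1) +=
            dz(n, j);
    // Xc buffer kept for reuse
    return dX;
  }
};

struct Block {
  Conv c1, c2, proj;
  bool has_proj = false;
  BN bn1, bn2;
  SE se;
  fmat m1, mout;  // ReLU masks

  void init(int cin, int f, int ratio, XRng& rng) {
    c1.init(3, 1, cin, f, rng);
    c2.init(3, 1, f, f, rng);
    bn1.init(f);
    bn2.init(f);
    se.init(f, ratio, rng);
    has_proj = cin != f;
    if (has_proj) proj.init(1, 1, cin, f, rng);
  }
  fmat forward(const fmat& X, int H, int W, int N, bool train) {
    fmat A = bn1.forward(c1.forward(X, H, W, N, train), train);
    relu_mask(A, m1, train);
    fmat B = se.forward(bn2.forward(c2.forward(A, H, W, N, train), train),
                        H * W, N, train);
    if (has_proj)
      B += proj.forward(X, H, W, N, train);
    else
      B += X;
    relu_mask(B, mout, train);
    return B;
  }
  fmat backward(fmat dY) {
    dY %= mout;
    // mout kept for reuse
    fmat dA = c2.backward(bn2.backward(se.backward(dY)));
    dA %= m1;
    // m1 kept for reuse
    fmat dX = c1.backward(bn1.backward(dA));
    if (has_proj)
      dX += proj.backward(dY);
    else
      dX += dY;
    return dX;
  }
};

struct Down {
  Conv cv;
  BN bn;
  fmat m;
  void init(int cin, int cout, XRng& rng) {
    cv.init(2, 2, cin, cout, rng);
    bn.init(cout);
  }
  fmat forward(const fmat& X, int H, int W, int N, bool train) {
    fmat Y = bn.forward(cv.forward(X, H, W, N, train), train);
    relu_mask(Y, m, train);
    return Y;
  }
  fmat backward(fmat dY) {
    dY %= m;
    // m kept for reuse
    return cv.backward(bn.backward(dY));
  }
};

struct CNet {
  int B, f0, ratio, K, cin = 3;
  std::vector<Block> blocks;
  std::vector<Down> downs;
  Conv head;
  fmat P;      // cached softmax output (training step)
  int lastH = 0, lastW = 0, lastN = 0;

  CNet(int B_, int f0_, int ratio_, int K_, uint64_t seed)
      : B(B_), f0(f0_), ratio(ratio_), K(K_) {
    XRng rng(seed);
    blocks.resize(B);
    downs.resize(B - 1);
    int c = cin;
    for (int b = 0; b < B; ++b) {
      int f = f0 << b;
      blocks[b].init(c, f, ratio, rng);
      c = f;
      if (b < B - 1) {
        int fn = f0 << (b + 1);
        downs[b].init(c, fn, rng);
        c = fn;
      }
    }
    // NOTE: feature width entering block b+1 equals the width set by the
    // downsampling convolution, so block b+1 has no projection path.
    head.init(1, 1, f0 << (B - 1), K, rng);
  }

  fmat forward(const fmat& X0, int H, int W, int N, bool train) {
    fmat X = blocks[0].forward(X0, H, W, N, train);
    for (int b = 1; b < B; ++b) {
      X = downs[b - 1].forward(X, H, W, N, train);
      H /= 2;
      W /= 2;
      X = blocks[b].forward(X, H, W, N, train);
    }
    X = head.forward(X, H, W, N, train);
    // per-pixel softmax over channels (column-wise passes)
    arma::fvec mx = arma::max(X, 1);
    arma::fvec ssum(X.n_rows, arma::fill::zeros);
    for (int k = 0; k < K; ++k) {
      X.col(k) = arma::exp(X.col(k) - mx);
      ssum += X.col(k);
    }
    for (int k = 0; k < K; ++k) X.col(k) /= ssum;
    lastH = H;
    lastW = W;
    lastN = N;
    return X;
  }

  void backward(const fmat& G) {
    // through softmax: dz = p .* (g - <g,p>)
    arma::fvec dots(P.n_rows, arma::fill::zeros);
    for (int k = 0; k < K; ++k) dots += G.col(k) % P.col(k);
    fmat dZ(P.n_rows, K);
    for (int k = 0; k < K; ++k) dZ.col(k) = P.col(k) % (G.col(k) - dots);
    fmat dX = head.backward(dZ);
    for (int b = B - 1; b >= 1; --b) {
      dX = blocks[b].backward(dX);
      dX = downs[b - 1].backward(dX);
    }
    blocks[0].backward(dX);
  }

  void collect(std::vector<std::pair<std::string, Param*>>& out) {
    for (int b = 0; b < B; ++b) {
      std::string p = "block" + std::to_string(b + 1) + "_";
      Block& bl = blocks[b];
      out.push_back({p + "conv1_W", &bl.c1.W});
      out.push_back({p + "conv1_b", &bl.c1.b});
      out.push_back({p + "bn1_gamma", &bl.bn1.g});
      out.push_back({p + "bn1_beta", &bl.bn1.bt});
      out.push_back({p + "conv2_W", &bl.c2.W});
      out.push_back({p + "conv2_b", &bl.c2.b});
      out.push_back({p + "bn2_gamma", &bl.bn2.g});
      out.push_back({p + "bn2_beta", &bl.bn2.bt});
      out.push_back({p + "se_W1", &bl.se.W1});
      out.push_back({p + "se_b1", &bl.se.b1});
      out.push_back({p + "se_W2", &bl.se.W2});
      out.push_back({p + "se_b2", &bl.se.b2});
      if (bl.has_proj) {
        out.push_back({p + "proj_W", &bl.proj.W});
        out.push_back({p + "proj_b", &bl.proj.b});
      }
      if (b < B - 1) {
        std::string d = "down" + std::to_string(b + 1) + "_";
        out.push_back({d + "conv_W", &downs[b].cv.W});
        out.push_back({d + "conv_b", &downs[b].cv.b});
        out.push_back({d + "bn_gamma", &downs[b].bn.g});
        out.push_back({d + "bn_beta", &downs[b].bn.bt});
      }
    }
    out.push_back({"head_W", &head.W});
    out.push_back({"head_b", &head.b});
  }
  std::vector<std::pair<std::string, frowvec*>> bnstats() {
    std::vector<std::pair<std::string, frowvec*>> out;
    for (int b = 0; b < B; ++b) {
      std::string p = "block" + std::to_string(b + 1) + "_";
      out.push_back({p + "bn1_rmean", &blocks[b].bn1.rmean});
      out.push_back({p + "bn1_rvar", &blocks[b].bn1.rvar});
      out.push_back({p + "bn2_rmean", &blocks[b].bn2.rmean});
      out.push_back({p + "bn2_rvar", &blocks[b].bn2.rvar});
      if (b < B - 1) {
        std::string d = "down" + std::to_string(b + 1) + "_";
        out.push_back({d + "bn_rmean", &downs[b].bn.rmean});
        out.push_back({d + "bn_rvar", &downs[b].bn.rvar});
      }
    }
    return out;
  }
};

// (H, W, C, N) R array -> (N*H*W, C) fmat
fmat array_to_act(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d.size() == 4 ? d[3] : 1;
  arma::uword HW = (arma::uword)H * W;
  fmat X(HW * N, C);
  const double* src = x.begin();
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < C; ++ch) {
      const double* s = src + ((arma::uword)n * C + ch) * HW;
      float* dptr = X.colptr(ch) + (arma::uword)n * HW;
      for (arma::uword i = 0; i < HW; ++i) dptr[i] = (float)s[i];
    }
  return X;
}

NumericVector act_to_array(const fmat& P, int H, int W, int N) {
  int K = P.n_cols;
  arma::uword HW = (arma::uword)H * W;
  NumericVector out(HW * K * N);
  out.attr("dim") = IntegerVector::create(H, W, K, N);
  double* dst = out.begin();
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      const float* s = P.colptr(k) + (arma::uword)n * HW;
      double* dptr = dst + ((arma::uword)n * K + k) * HW;
      for (arma::uword i = 0; i < HW; ++i) dptr[i] = (double)s[i];
    }
  return out;
}

}  // namespace

// [[Rcpp::export]]
SEXP cnet_create(int n_blocks, int base_features, int se_ratio, int n_classes,
                 double seed) {
#if defined(__GLIBC__)
  // large activation buffers are allocated every iteration; keep them on the
  // heap instead of mmap so freed blocks are reused without kernel zeroing
  static bool tuned = false;
  if (!tuned) {
    mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
    tuned = true;
  }
#endif
  XPtr<CNet> p(new CNet(n_blocks, base_features, se_ratio, n_classes,
                        (uint64_t)seed),
               true);
  return p;
}

// [[Rcpp::export]]
NumericVector cnet_forward(SEXP ptr, NumericVector x, bool train = false) {
  XPtr<CNet> net(ptr);
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], N = d.size() == 4 ? d[3] : 1;
  fmat X = array_to_act(x);
  fmat P = net->forward(X, H, W, N, train);
  return act_to_array(P, net->lastH, net->lastW, N);
}

// [[Rcpp::export]]
double cnet_train_step(SEXP ptr, NumericVector x, NumericVector y,
                       NumericVector w, double eps, double lr, double momentum,
                       double weight_decay) {
  XPtr<CNet> net(ptr);
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], N = d.size() == 4 ? d[3] : 1;
  fmat X = array_to_act(x);
  fmat P = net->forward(X, H, W, N, true);
  net->P = P;
  fmat Y = array_to_act(y);
  int K = net->K;
  arma::uword OHW = (arma::uword)net->lastH * net->lastW;
  // weighted soft Dice loss and its gradient wrt the softmax output
  double loss = 0;
  fmat G(P.n_rows, K, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::uword a = (arma::uword)n * OHW, b = (arma::uword)(n + 1) * OHW - 1;
    for (int k = 0; k < K; ++k) {
      double A = 2.0 * arma::dot(arma::conv_to<arma::fvec>::from(Y(arma::span(a, b), k)),
                                 arma::conv_to<arma::fvec>::from(P(arma::span(a, b), k)));
      double Bden =
          arma::accu(Y(arma::span(a, b), k)) + arma::accu(P(arma::span(a, b), k)) + eps;
      loss -= w[k] * A / Bden / N;
      float coef = (float)(-w[k] / (double)N / (Bden * Bden));
      G(arma::span(a, b), k) =
          coef * (2.0f * (float)Bden * Y(arma::span(a, b), k) - (float)A);
    }
  }
  net->backward(G);
  std::vector<std::pair<std::string, Param*>> ps;
  net->collect(ps);
  for (auto& pr : ps) {
    Param* pm = pr.second;
    if (weight_decay > 0) pm->G += (float)weight_decay * pm->W;
    pm->V = (float)momentum * pm->V - (float)lr * pm->G;
    pm->W += pm->V;
    pm->G.zeros();
  }
  return loss;
}

// [[Rcpp::export]]
double cnet_nparams(SEXP ptr) {
  XPtr<CNet> net(ptr);
  std::vector<std::pair<std::string, Param*>> ps;
  net->collect(ps);
  double n = 0;
  for (auto& pr : ps) n += pr.second->W.n_elem;
  return n;
}

// [[Rcpp::export]]
List cnet_get_weights(SEXP ptr) {
  XPtr<CNet> net(ptr);
  std::vector<std::pair<std::string, Param*>> ps;
  net->collect(ps);
  List out;
  for (auto& pr : ps) {
    fmat& Wm = pr.second->W;
    NumericMatrix m(Wm.n_rows, Wm.n_cols);
    for (arma::uword i = 0; i < Wm.n_elem; ++i) m[i] = Wm(i);
    out[pr.first] = m;
  }
  for (auto& pr : net->bnstats()) {
    frowvec& v = *pr.second;
    NumericVector m(v.n_elem);
    for (arma::uword i = 0; i < v.n_elem; ++i) m[i] = v(i);
    out[pr.first] = m;
  }
  return out;
}

// [[Rcpp::export]]
void cnet_set_weights(SEXP ptr, List weights) {
  XPtr<CNet> net(ptr);
  std::vector<std::pair<std::string, Param*>> ps;
  net->collect(ps);
  for (auto& pr : ps) {
    if (!weights.containsElementNamed(pr.first.c_str()))
      stop("missing weight: %s", pr.first);
    NumericMatrix m = weights[pr.first];
    fmat& Wm = pr.second->W;
    if ((arma::uword)m.nrow() != Wm.n_rows || (arma::uword)m.ncol() != Wm.n_cols)
      stop("shape mismatch for weight: %s", pr.first);
    for (arma::uword i = 0; i < Wm.n_elem; ++i) Wm(i) = (float)m[i];
    pr.second->V.zeros();
    pr.second->G.zeros();
  }
  for (auto& pr : net->bnstats()) {
    if (!weights.containsElementNamed(pr.first.c_str()))
      stop("missing weight: %s", pr.first);
    NumericVector m = weights[pr.first];
    frowvec& v = *pr.second;
    if ((arma::uword)m.size() != v.n_elem)
      stop("shape mismatch for weight: %s", pr.first);
    for (arma::uword i = 0; i < v.n_elem; ++i) v(i) = (float)m[i];
  }
}

// [[Rcpp::export]]
List cnet_describe(SEXP ptr) {
  XPtr<CNet> net(ptr);
  return List::create(_["n_blocks"] = net->B, _["base_features"] = net->f0,
                      _["se_ratio"] = net->ratio, _["n_classes"] = net->K);
}
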