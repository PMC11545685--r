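// Single-precision convolutional network engine for the weighted attention
// U-Net.  Layout convention: a batch activation is an arma::fmat with one row
// per pixel and one column per channel; pixel row index p = n*H*W + r + c*H
// (i.e. each image is stored in R's column-major order), which lets frames
// arriving from R as (H, W, N) arrays be used without reshuffling.
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using namespace Rcpp;

// The engine allocates and frees large scratch buffers (im2col matrices) on
// every step; keep them on the heap instead of round-tripping through mmap,
// which costs a page fault per touched page on each reallocation.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 29);
    done = true;
  }
#endif
}
using arma::fmat;
using arma::frowvec;
using arma::uword;

// ---------------------------------------------------------------------------
// primitives
// ---------------------------------------------------------------------------

// im2col for a 3x3 kernel with unit zero padding.
// X: (N*H*W, cin) -> col: (N*H*W, cin*9); column q = ci*9 + (dc+1)*3 + (dr+1).
static fmat im2col3(const fmat& X, int N, int H, int W) {
  const int HW = H * W;
  const int cin = (int)X.n_cols;
  fmat col((uword)N * HW, (uword)cin * 9);
  for (int ci = 0; ci < cin; ++ci) {
    const float* xc = X.colptr(ci);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int off = (dc + 1) * 3 + (dr + 1);
        float* cc_ptr = col.colptr((uword)ci * 9 + off);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int n = 0; n < N; ++n) {
          const size_t base = (size_t)n * HW;
          for (int c = 0; c < W; ++c) {
            const int cc = c + dc;
            float* dst = cc_ptr + base + (size_t)c * H;
            if (cc < 0 || cc >= W) {          // fully out of bounds
              std::memset(dst, 0, sizeof(float) * (size_t)H);
              continue;
            }
            if (r0 > 0) dst[0] = 0.f;
            if (r1 < H) dst[H - 1] = 0.f;
            std::memcpy(dst + r0, xc + base + (size_t)cc * H + (r0 + dr),
                        sizeof(float) * (size_t)(r1 - r0));
          }
        }
      }
    }
  }
  return col;
}

// Rearranged kernel for the backward data pass: the gradient w.r.t. the
// input of a same-padded 3x3 correlation is itself a same-padded 3x3
// correlation of dY with the kernels rotated by 180 degrees.
static fmat rotate_kernel(const fmat& W, int cin, int cout) {
  fmat Wr((uword)cout * 9, (uword)cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < cout; ++co)
      for (int off = 0; off < 9; ++off)
        Wr((uword)co * 9 + off, ci) = W(co, (uword)ci * 9 + (8 - off));
  return Wr;
}

// 2x2 stride-2 max pool; idx records the winning source row for backward.
static fmat maxpool2(const fmat& X, int N, int H, int W, arma::umat& idx) {
  const int Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  const int C = (int)X.n_cols;
  fmat Y((uword)N * HWo, (uword)C);
  idx.set_size((uword)N * HWo, (uword)C);
  for (int ch = 0; ch < C; ++ch) {
    const float* xc = X.colptr(ch);
    float* yc = Y.colptr(ch);
    uword* ic = idx.colptr(ch);
    for (int n = 0; n < N; ++n) {
      const size_t bi = (size_t)n * HW, bo = (size_t)n * HWo;
      for (int c = 0; c < Wo; ++c) {
        for (int r = 0; r < Ho; ++r) {
          const size_t p00 = bi + (size_t)(2 * c) * H + 2 * r;
          size_t best = p00;
          float v = xc[p00];
          const size_t cand[3] = {p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (xc[cand[k]] > v) { v = xc[cand[k]]; best = cand[k]; }
          const size_t po = bo + (size_t)c * Ho + r;
          yc[po] = v;
          ic[po] = (uword)best;
        }
      }
    }
  }
  return Y;
}

static fmat maxpool2_bwd(const fmat& dY, const arma::umat& idx, uword nrow_in) {
  fmat dX(nrow_in, dY.n_cols, arma::fill::zeros);
  for (uword ch = 0; ch < dY.n_cols; ++ch) {
    const float* dyc = dY.colptr(ch);
    const uword* ic = idx.colptr(ch);
    float* dxc = dX.colptr(ch);
    for (uword p = 0; p < dY.n_rows; ++p) dxc[ic[p]] += dyc[p];
  }
  return dX;
}

// Nearest-neighbour x2 upsample.
static fmat upsample2(const fmat& X, int N, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  const int C = (int)X.n_cols;
  fmat Y((uword)N * HWo, (uword)C);
  for (int ch = 0; ch < C; ++ch) {
    const float* xc = X.colptr(ch);
    float* yc = Y.colptr(ch);
    for (int n = 0; n < N; ++n) {
      const size_t bi = (size_t)n * HW, bo = (size_t)n * HWo;
      for (int c = 0; c < Wo; ++c)
        for (int r = 0; r < Ho; ++r)
          yc[bo + (size_t)c * Ho + r] = xc[bi + (size_t)(c / 2) * H + r / 2];
    }
  }
  return Y;
}

static fmat upsample2_bwd(const fmat& dY, int N, int H, int W) {
  // H, W are the *input* (coarse) sides.
  const int Ho = 2 * H, HW = H * W, HWo = 4 * HW;
  const int C = (int)dY.n_cols;
  fmat dX((uword)N * HW, (uword)C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const float* dyc = dY.colptr(ch);
    float* dxc = dX.colptr(ch);
    for (int n = 0; n < N; ++n) {
      const size_t bi = (size_t)n * HW, bo = (size_t)n * HWo;
      for (int c = 0; c < 2 * W; ++c)
        for (int r = 0; r < Ho; ++r)
          dxc[bi + (size_t)(c / 2) * H + r / 2] += dyc[bo + (size_t)c * Ho + r];
    }
  }
  return dX;
}

static inline void relu_(fmat& X) { X.transform([](float v) { return v > 0.f ? v : 0.f; }); }

static inline void relu_bwd_(fmat& dY, const fmat& Ypost) {
  for (uword i = 0; i < dY.n_elem; ++i)
    if (Ypost[i] <= 0.f) dY[i] = 0.f;
}

static inline fmat sigmoid(const fmat& X) {
  fmat Y = X;
  Y.transform([](float v) { return 1.f / (1.f + std::exp(-v)); });
  return Y;
}

// ---------------------------------------------------------------------------
// layers
// ---------------------------------------------------------------------------

struct Conv {
  fmat W;          // (cout, cin*k*k)
  frowvec b;       // (cout)
  int k;           // 1 or 3
  fmat gW, mW, vW; // gradient and Adam moments
  frowvec gb, mb, vb;

  void init_opt() {
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
    gW.zeros(W.n_rows, W.n_cols); gb.zeros(b.n_elem);
  }
};

// Forward/backward caches for one conv application.
struct ConvUse {
  fmat col;   // stored input (im2col for k=3, plain input for k=1)
  fmat out;   // post-activation output (for ReLU mask); empty if linear
};

static fmat conv_fwd(Conv& cv, ConvUse& use, const fmat& X,
                     int N, int H, int W, bool relu) {
  if (cv.k == 3) use.col = im2col3(X, N, H, W); else use.col = X;
  fmat Y = use.col * cv.W.t();
  Y.each_row() += cv.b;
  if (relu) { relu_(Y); use.out = Y; } else use.out.reset();
  return Y;
}

// dY is consumed; returns gradient w.r.t. the conv input (empty matrix when
// `need_dx` is false, e.g. for layers whose input is a network input).
static fmat conv_bwd(Conv& cv, ConvUse& use, fmat dY,
                     int N, int H, int W, int cin, bool need_dx = true) {
  if (!use.out.is_empty()) relu_bwd_(dY, use.out);
  cv.gW += dY.t() * use.col;
  cv.gb += arma::sum(dY, 0);
  if (!need_dx) return fmat();
  if (cv.k == 3) {
    const int cout = (int)cv.W.n_rows;
    return im2col3(dY, N, H, W) * rotate_kernel(cv.W, cin, cout);
  }
  return dY * cv.W;
}

// ---------------------------------------------------------------------------
// the network
// ---------------------------------------------------------------------------

struct NetConfig {
  std::vector<int> ef; // 5 encoder filter counts
  int att;             // weighted-block channel width
  std::vector<int> df; // 4 decoder filter counts (levels 4,3,2,1)
  int head;            // head conv width
};

static const char* LAYER_NAMES[] = {
  "enc1", "enc2", "enc3", "enc4", "enc5",
  "wb1_proj", "wb1_lift", "wb1_ref", "wb1_gate",
  "wb2_proj", "wb2_lift", "wb2_ref", "wb2_gate",
  "wb3_proj", "wb3_lift", "wb3_ref", "wb3_gate",
  "wb4_proj", "wb4_lift", "wb4_ref", "wb4_gate",
  "dec4_a", "dec4_b", "dec3_a", "dec3_b",
  "dec2_a", "dec2_b", "dec1_a", "dec1_b",
  "head_a", "head_b"
};
static const int N_LAYERS = 31;

class WUNet {
public:
  NetConfig cfg;
  std::vector<Conv> L; // indexed per LAYER_NAMES
  long t_adam = 0;

  // ---- caches for one batch (overwritten per call) ----
  int N = 0, S = 0;
  ConvUse uE[5], uProj[4], uLift[4], uRef[4], uGate[4];
  ConvUse uDecA[4], uDecB[4], uHeadA, uHeadB; // uDec*[i] holds level 4-i
  arma::umat pidxL[4], pidxP[4];              // encoder pools, block pools
  fmat Lact[5];                               // post-ReLU encoder maps
  fmat Q[4], X[4];                            // per-block gate pieces
  fmat prob;                                  // final probabilities

  explicit WUNet(const NetConfig& c) : cfg(c) {}

  // expected (cin, cout, k) per layer, in LAYER_NAMES order
  std::vector<std::array<int, 3>> layer_dims() const {
    const std::vector<int>& f = cfg.ef;
    const int a = cfg.att;
    const std::vector<int>& d = cfg.df;
    std::vector<std::array<int, 3>> v;
    v.push_back({1, f[0], 3});
    v.push_back({f[0], f[1], 3});
    v.push_back({f[1], f[2], 3});
    v.push_back({f[2], f[3], 3});
    v.push_back({f[3], f[4], 3});
    const int z[4] = {f[0], f[1], f[2], f[3]};
    for (int l = 0; l < 4; ++l) {
      v.push_back({z[l], a, 1});
      v.push_back({1, a, 1});
      v.push_back({a, a, 3});
      v.push_back({a, 1, 1});
    }
    v.push_back({f[4] + a, d[0], 3});
    v.push_back({d[0], d[0], 3});
    v.push_back({d[0] + a, d[1], 3});
    v.push_back({d[1], d[1], 3});
    v.push_back({d[1] + a, d[2], 3});
    v.push_back({d[2], d[2], 3});
    v.push_back({d[2] + a, d[3], 3});
    v.push_back({d[3], d[3], 3});
    v.push_back({d[3], cfg.head, 3});
    v.push_back({cfg.head, 1, 1});
    return v;
  }

  double n_parameters() const {
    double n = 0;
    for (const Conv& cv : L) n += (double)cv.W.n_elem + cv.b.n_elem;
    return n;
  }

  // forward pass; frames/wmap are (N*S*S, 1)
  fmat forward(const fmat& frames, const fmat& wmap, int N_, int S_) {
    N = N_; S = S_;
    const int s2 = S / 2, s4 = S / 4, s8 = S / 8, s16 = S / 16;

    // weight-map pyramid w_l at sides S/2^l
    arma::umat dummy;
    fmat w1 = maxpool2(wmap, N, S, S, dummy);
    fmat w2 = maxpool2(w1, N, s2, s2, dummy);
    fmat w3 = maxpool2(w2, N, s4, s4, dummy);
    fmat w4 = maxpool2(w3, N, s8, s8, dummy);
    const fmat* wl[4] = {&w1, &w2, &w3, &w4};
    const int side_l[5] = {S, s2, s4, s8, s16};

    // encoder
    fmat cur = frames;
    for (int i = 0; i < 5; ++i) {
      const int sd = side_l[i];
      Lact[i] = conv_fwd(L[i], uE[i], cur, N, sd, sd, true);
      if (i < 4) cur = maxpool2(Lact[i], N, sd, sd, pidxL[i]);
    }

    // weighted blocks: P = proj(LFM); Q = pool(P); U = relu(lift(w_l));
    // A = Q + U; R = relu(ref3x3(A)); X = sigmoid(gate(R)); O = X * Q
    fmat O[4];
    for (int l = 0; l < 4; ++l) {
      const int sd = side_l[l], so = side_l[l + 1];
      const int base = 5 + 4 * l;
      fmat P = conv_fwd(L[base], uProj[l], Lact[l], N, sd, sd, false);
      Q[l] = maxpool2(P, N, sd, sd, pidxP[l]);
      fmat U = conv_fwd(L[base + 1], uLift[l], *wl[l], N, so, so, true);
      fmat A = Q[l] + U;
      fmat R = conv_fwd(L[base + 2], uRef[l], A, N, so, so, true);
      X[l] = sigmoid(conv_fwd(L[base + 3], uGate[l], R, N, so, so, false));
      O[l] = Q[l];
      O[l].each_col() %= X[l].col(0);
    }

    // decoder: concat gated skip, two 3x3 convs, upsample x2
    fmat d = Lact[4]; // bottleneck at S/16
    for (int i = 0; i < 4; ++i) {
      const int l = 3 - i;              // block level 4,3,2,1
      const int sd = side_l[l + 1];     // current side
      fmat cat = arma::join_rows(d, O[l]);
      fmat t = conv_fwd(L[21 + 2 * i], uDecA[i], cat, N, sd, sd, true);
      t = conv_fwd(L[22 + 2 * i], uDecB[i], t, N, sd, sd, true);
      d = upsample2(t, N, sd, sd);
    }
    fmat h = conv_fwd(L[29], uHeadA, d, N, S, S, true);
    fmat z = conv_fwd(L[30], uHeadB, h, N, S, S, false);
    prob = sigmoid(z);
    return prob;
  }

  // loss + gradient w.r.t. logits for the configured loss on the cached batch
  double loss_and_dz(const fmat& mask, const std::string& kind, fmat& dz) {
    const int HW = S * S;
    const float eps = 1e-6f;
    const bool use_bce = (kind == "bce" || kind == "bce_dice");
    const bool use_dice = (kind == "dice" || kind == "bce_dice");
    dz.zeros(prob.n_rows, 1);
    double loss = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t b0 = (size_t)n * HW;
      double Spm = 0, Sp = 0, Sm = 0, bce = 0;
      for (int i = 0; i < HW; ++i) {
        const float p = prob[b0 + i], m = mask[b0 + i];
        Spm += (double)p * m; Sp += p; Sm += m;
        if (use_bce) {
          const float pc = std::min(std::max(p, 1e-7f), 1.f - 1e-7f);
          bce += -(m * std::log(pc) + (1.f - m) * std::log(1.f - pc));
        }
      }
      const double denom = Sp + Sm + eps, numer = 2.0 * Spm + eps;
      if (use_dice) loss += (1.0 - numer / denom) / N;
      if (use_bce) loss += bce / HW / N;
      for (int i = 0; i < HW; ++i) {
        const float p = prob[b0 + i], m = mask[b0 + i];
        float g = 0.f;
        if (use_bce) g += (p - m) / (float)HW;            // d(bce)/dz
        if (use_dice) {
          const float dDdp = -(float)((2.0 * m * denom - numer) / (denom * denom));
          g += dDdp * p * (1.f - p);
        }
        dz[b0 + i] = g / N;
      }
    }
    return loss;
  }

  void backward(const fmat& dz) {
    const int s2 = S / 2, s4 = S / 4, s8 = S / 8, s16 = S / 16;
    const int side_l[5] = {S, s2, s4, s8, s16};
    for (Conv& cv : L) { cv.gW.zeros(); cv.gb.zeros(); }

    fmat dh = conv_bwd(L[30], uHeadB, dz, N, S, S, cfg.head);
    fmat dd = conv_bwd(L[29], uHeadA, dh, N, S, S, cfg.df[3]);

    fmat dO[4], dLfromProj[4];
    for (int i = 3; i >= 0; --i) {
      const int l = 3 - i;               // block level index 0..3 (level l+1)
      const int sd = side_l[l + 1];
      // dd arrives at side 2*sd (after this stage's upsample)
      fmat dt = upsample2_bwd(dd, N, sd, sd);
      const int dch = cfg.df[i];
      dt = conv_bwd(L[22 + 2 * i], uDecB[i], dt, N, sd, sd, dch);
      const int cin_a = (i == 0 ? cfg.ef[4] : cfg.df[i - 1]) + cfg.att;
      fmat dcat = conv_bwd(L[21 + 2 * i], uDecA[i], dt, N, sd, sd, cin_a);
      const int dprev = cin_a - cfg.att;
      dd = dcat.cols(0, dprev - 1);
      dO[l] = dcat.cols(dprev, dcat.n_cols - 1);
    }
    // dd now is the bottleneck gradient
    fmat dcur = dd;

    // weighted blocks backward (accumulate into encoder LFM grads)
    for (int l = 3; l >= 0; --l) {
      const int sd = side_l[l], so = side_l[l + 1];
      const int base = 5 + 4 * l;
      // O = Q * X  ->  dQ += X*dO ; dXgate = sum_ch(Q*dO)
      fmat dQ = dO[l];
      dQ.each_col() %= X[l].col(0);
      fmat dXg = arma::sum(dO[l] % Q[l], 1); // (NP,1)
      // sigmoid
      fmat dzg = dXg % X[l].col(0) % (1.f - X[l].col(0));
      fmat dR = conv_bwd(L[base + 3], uGate[l], dzg, N, so, so, cfg.att);
      fmat dA = conv_bwd(L[base + 2], uRef[l], dR, N, so, so, cfg.att);
      // A = Q + U
      dQ += dA;
      conv_bwd(L[base + 1], uLift[l], dA, N, so, so, 1, false); // w_l: no grad
      fmat dP = maxpool2_bwd(dQ, pidxP[l], (uword)N * sd * sd);
      const int z_l = cfg.ef[l];
      dLfromProj[l] = conv_bwd(L[base], uProj[l], dP, N, sd, sd, z_l);
    }

    // encoder backward
    for (int i = 4; i >= 0; --i) {
      const int sd = side_l[i];
      fmat dL = dcur; // gradient w.r.t. post-ReLU L[i]
      if (i < 4) dL = maxpool2_bwd(dcur, pidxL[i], (uword)N * sd * sd);
      if (i < 4) dL += dLfromProj[i];
      const int cin = (i == 0) ? 1 : cfg.ef[i - 1];
      dcur = conv_bwd(L[i], uE[i], dL, N, sd, sd, cin, i > 0);
    }
  }

  void adam_step(double lr, double b1, double b2, double eps) {
    ++t_adam;
    const double c1 = 1.0 - std::pow(b1, (double)t_adam);
    const double c2 = 1.0 - std::pow(b2, (double)t_adam);
    for (Conv& cv : L) {
      cv.mW = (float)b1 * cv.mW + (float)(1 - b1) * cv.gW;
      cv.vW = (float)b2 * cv.vW + (float)(1 - b2) * arma::square(cv.gW);
      cv.W -= (float)lr * (cv.mW / (float)c1) /
              (arma::sqrt(cv.vW / (float)c2) + (float)eps);
      cv.mb = (float)b1 * cv.mb + (float)(1 - b1) * cv.gb;
      cv.vb = (float)b2 * cv.vb + (float)(1 - b2) * arma::square(cv.gb);
      cv.b -= (float)lr * (cv.mb / (float)c1) /
              (arma::sqrt(cv.vb / (float)c2) + (float)eps);
    }
  }

  void free_caches() {
    for (int i = 0; i < 5; ++i) { uE[i] = ConvUse(); Lact[i].reset(); }
    for (int l = 0; l < 4; ++l) {
      uProj[l] = ConvUse(); uLift[l] = ConvUse();
      uRef[l] = ConvUse(); uGate[l] = ConvUse();
      uDecA[l] = ConvUse(); uDecB[l] = ConvUse();
      Q[l].reset(); X[l].reset();
      pidxL[l].reset(); pidxP[l].reset();
    }
    uHeadA = ConvUse(); uHeadB = ConvUse();
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static NetConfig cfg_from_list(const List& cfg) {
  NetConfig c;
  c.ef = as<std::vector<int>>(cfg["encoder_filters"]);
  if (c.ef.size() != 5) stop("encoder_filters must have length 5");
  c.att = as<int>(cfg["attention_channels"]);
  c.df = as<std::vector<int>>(cfg["decoder_filters"]);
  if (c.df.size() != 4) stop("decoder_filters must have length 4");
  c.head = as<int>(cfg["head_channels"]);
  return c;
}

static void set_weights_impl(WUNet& net, const List& weights) {
  auto dims = net.layer_dims();
  net.L.clear();
  net.L.resize(N_LAYERS);
  for (int i = 0; i < N_LAYERS; ++i) {
    if (!weights.containsElementNamed(LAYER_NAMES[i]))
      stop("missing weights for layer '%s'", LAYER_NAMES[i]);
    List w = weights[LAYER_NAMES[i]];
    NumericMatrix W = w["W"];
    NumericVector b = w["b"];
    const int cin = dims[i][0], cout = dims[i][1], k = dims[i][2];
    if (W.nrow() != cout || W.ncol() != cin * k * k || b.size() != cout)
      stop("layer '%s': expected W %d x %d, b length %d", LAYER_NAMES[i],
           cout, cin * k * k, cout);
    Conv cv;
    cv.k = k;
    cv.W = arma::conv_to<fmat>::from(as<arma::mat>(W));
    cv.b = arma::conv_to<frowvec>::from(as<arma::rowvec>(b));
    cv.init_opt();
    net.L[i] = std::move(cv);
  }
}

// [[Rcpp::export]]
SEXP cpp_net_create(List cfg, List weights) {
  tune_allocator();
  XPtr<WUNet> p(new WUNet(cfg_from_list(cfg)), true);
  set_weights_impl(*p, weights);
  return p;
}

static fmat array_to_batch(const NumericVector& x, int& H, int& W, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 2) { H = d[0]; W = d[1]; N = 1; }
  else if (d.size() == 3) { H = d[0]; W = d[1]; N = d[2]; }
  else stop("expected a (H, W) matrix or (H, W, N) array");
  fmat out((uword)x.size(), 1);
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

static NumericVector batch_to_array(const fmat& p, int H, int W, int N) {
  NumericVector out(p.n_elem);
  for (uword i = 0; i < p.n_elem; ++i) out[i] = p[i];
  out.attr("dim") = IntegerVector::create(H, W, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_net_forward(SEXP ptr, NumericVector frames, NumericVector wmaps) {
  XPtr<WUNet> net(ptr);
  int H, W, N, H2, W2, N2;
  fmat x = array_to_batch(frames, H, W, N);
  fmat w = array_to_batch(wmaps, H2, W2, N2);
  if (H != W) stop("frames must be square");
  if (H % 16 != 0) stop("frame side must be divisible by 16");
  if (H != H2 || W != W2 || N != N2) stop("weight maps must match frames");
  fmat p = net->forward(x, w, N, H);
  NumericVector out = batch_to_array(p, H, W, N);
  net->free_caches();
  return out;
}

// Forward with per-level diagnostics (gate values, gated-skip dimensions).
// [[Rcpp::export]]
List cpp_net_forward_debug(SEXP ptr, NumericVector frames, NumericVector wmaps) {
  XPtr<WUNet> net(ptr);
  int H, W, N, H2, W2, N2;
  fmat x = array_to_batch(frames, H, W, N);
  fmat w = array_to_batch(wmaps, H2, W2, N2);
  if (H != H2 || N != N2) stop("weight maps must match frames");
  fmat p = net->forward(x, w, N, H);
  List gates(4), odims(4);
  for (int l = 0; l < 4; ++l) {
    const int so = H >> (l + 1);
    NumericVector g = batch_to_array(net->X[l], so, so, N);
    gates[l] = g;
    odims[l] = IntegerVector::create(so, so, (int)net->Q[l].n_cols);
  }
  List out = List::create(_["prob"] = batch_to_array(p, H, W, N),
                          _["gates"] = gates, _["skip_dims"] = odims);
  net->free_caches();
  return out;
}

// [[Rcpp::export]]
double cpp_net_train_step(SEXP ptr, NumericVector frames, NumericVector wmaps,
                          NumericVector masks, std::string loss, double lr,
                          double beta1, double beta2, double eps) {
  XPtr<WUNet> net(ptr);
  int H, W, N, H2, W2, N2, H3, W3, N3;
  fmat x = array_to_batch(frames, H, W, N);
  fmat w = array_to_batch(wmaps, H2, W2, N2);
  fmat m = array_to_batch(masks, H3, W3, N3);
  if (H != H2 || H != H3 || N != N2 || N != N3)
    stop("frames, weight maps and masks must share dimensions");
  net->forward(x, w, N, H);
  fmat dz;
  double lossval = net->loss_and_dz(m, loss, dz);
  net->backward(dz);
  net->adam_step(lr, beta1, beta2, eps);
  net->free_caches();
  return lossval;
}

// Loss and raw parameter gradients without an optimizer update; used to
// verify the analytic backward pass against finite differences.
// [[Rcpp::export]]
List cpp_net_loss_grad(SEXP ptr, NumericVector frames, NumericVector wmaps,
                       NumericVector masks, std::string loss) {
  XPtr<WUNet> net(ptr);
  int H, W, N, H2, W2, N2, H3, W3, N3;
  fmat x = array_to_batch(frames, H, W, N);
  fmat w = array_to_batch(wmaps, H2, W2, N2);
  fmat m = array_to_batch(masks, H3, W3, N3);
  net->forward(x, w, N, H);
  fmat dz;
  double lossval = net->loss_and_dz(m, loss, dz);
  net->backward(dz);
  List grads(N_LAYERS);
  CharacterVector nm(N_LAYERS);
  for (int i = 0; i < N_LAYERS; ++i) {
    const Conv& cv = net->L[i];
    NumericMatrix gW(cv.gW.n_rows, cv.gW.n_cols);
    for (uword j = 0; j < cv.gW.n_elem; ++j) gW[j] = cv.gW[j];
    NumericVector gb(cv.gb.n_elem);
    for (uword j = 0; j < cv.gb.n_elem; ++j) gb[j] = cv.gb[j];
    grads[i] = List::create(_["W"] = gW, _["b"] = gb);
    nm[i] = LAYER_NAMES[i];
  }
  grads.attr("names") = nm;
  net->free_caches();
  return List::create(_["loss"] = lossval, _["grads"] = grads);
}

// [[Rcpp::export]]
List cpp_net_get_weights(SEXP ptr) {
  XPtr<WUNet> net(ptr);
  List out(N_LAYERS);
  CharacterVector nm(N_LAYERS);
  for (int i = 0; i < N_LAYERS; ++i) {
    const Conv& cv = net->L[i];
    NumericMatrix W(cv.W.n_rows, cv.W.n_cols);
    for (uword j = 0; j < cv.W.n_elem; ++j) W[j] = cv.W[j];
    NumericVector b(cv.b.n_elem);
    for (uword j = 0; j < cv.b.n_elem; ++j) b[j] = cv.b[j];
    out[i] = List::create(_["W"] = W, _["b"] = b);
    nm[i] = LAYER_NAMES[i];
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_weights(SEXP ptr, List weights) {
  XPtr<WUNet> net(ptr);
  long t = net->t_adam;
  set_weights_impl(*net, weights);
  net->t_adam = t;
}

// [[Rcpp::export]]
double cpp_net_param_count(SEXP ptr) {
  XPtr<WUNet> net(ptr);
  return net->n_parameters();
}

// [[Rcpp::export]]
List cpp_net_layer_dims(SEXP ptr) {
  XPtr<WUNet> net(ptr);
  auto dims = net->layer_dims();
  List out(N_LAYERS);
  CharacterVector nm(N_LAYERS);
  for (int i = 0; i < N_LAYERS; ++i) {
    out[i] = IntegerVector::create(_["cin"] = dims[i][0],
                                   _["cout"] = dims[i][1],
                                   _["k"] = dims[i][2]);
    nm[i] = LAYER_NAMES[i];
  }
  out.attr("names") = nm;
  return out;
}

// ---------------------------------------------------------------------------
// standalone pieces used by tests and by the weight-map pyramid
// ---------------------------------------------------------------------------

// One weighted block in isolation.  lfm: (H, W, C); w: (H/2, W/2) pyramid
// level (a full-size map is pooled by the R wrapper before the call).
// [[Rcpp::export]]
List cpp_weighted_block(NumericVector lfm, NumericMatrix wmat, List wts) {
  IntegerVector d = lfm.attr("dim");
  if (d.size() != 3) stop("lfm must be an (H, W, C) array");
  const int H = d[0], W = d[1], C = d[2];
  if (wmat.nrow() != H / 2 || wmat.ncol() != W / 2)
    stop("weight map must be at half the feature-map side");
  fmat Xf((uword)H * W, (uword)C);
  for (R_xlen_t i = 0; i < lfm.size(); ++i) Xf[i] = (float)lfm[i];
  fmat wv((uword)(H / 2) * (W / 2), 1);
  for (R_xlen_t i = 0; i < wmat.size(); ++i) wv[i] = (float)wmat[i];

  auto getc = [&](const char* nm, int k) {
    List w = wts[nm];
    Conv cv;
    cv.k = k;
    cv.W = arma::conv_to<fmat>::from(as<arma::mat>(w["W"]));
    cv.b = arma::conv_to<frowvec>::from(as<arma::rowvec>(w["b"]));
    return cv;
  };
  Conv proj = getc("proj", 1), lift = getc("lift", 1),
       ref = getc("ref", 3), gate = getc("gate", 1);
  ConvUse u1, u2, u3, u4;
  fmat P = conv_fwd(proj, u1, Xf, 1, H, W, false);
  arma::umat pidx;
  fmat Q = maxpool2(P, 1, H, W, pidx);
  fmat U = conv_fwd(lift, u2, wv, 1, H / 2, W / 2, true);
  fmat A = Q + U;
  fmat R = conv_fwd(ref, u3, A, 1, H / 2, W / 2, true);
  fmat Xg = sigmoid(conv_fwd(gate, u4, R, 1, H / 2, W / 2, false));
  fmat O = Q;
  O.each_col() %= Xg.col(0);
  const int a = (int)Q.n_cols;
  NumericVector Oarr(O.n_elem), Qarr(Q.n_elem);
  for (uword i = 0; i < O.n_elem; ++i) Oarr[i] = O[i];
  for (uword i = 0; i < Q.n_elem; ++i) Qarr[i] = Q[i];
  Oarr.attr("dim") = IntegerVector::create(H / 2, W / 2, a);
  Qarr.attr("dim") = IntegerVector::create(H / 2, W / 2, a);
  NumericMatrix Xout(H / 2, W / 2);
  for (int i = 0; i < (H / 2) * (W / 2); ++i) Xout[i] = Xg[i];
  return List::create(_["O"] = Oarr, _["X"] = Xout, _["Q"] = Qarr);
}

// 2x2 stride-2 max pool of a single matrix (used for the weight-map
// pyramid).  Computed in double precision so values pass through exactly.
// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_mat(NumericMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  if (H % 2 != 0 || W % 2 != 0) stop("sides must be even");
  NumericMatrix out(H / 2, W / 2);
  for (int c = 0; c < W / 2; ++c)
    for (int r = 0; r < H / 2; ++r)
      out(r, c) = std::max(std::max(x(2 * r, 2 * c), x(2 * r + 1, 2 * c)),
                           std::max(x(2 * r, 2 * c + 1),
                                    x(2 * r + 1, 2 * c + 1)));
  return out;
}

// Plain 3x3 same-padding convolution of an (H, W, Cin) array; used to verify
// the GEMM path against a direct R loop in the tests.
// [[Rcpp::export]]
NumericVector cpp_conv3x3(NumericVector x, NumericMatrix Wm, NumericVector b) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("x must be an (H, W, C) array");
  const int H = d[0], W = d[1], C = d[2];
  if (Wm.ncol() != C * 9) stop("W must have cin*9 columns");
  fmat X((uword)H * W, (uword)C);
  for (R_xlen_t i = 0; i < x.size(); ++i) X[i] = (float)x[i];
  Conv cv;
  cv.k = 3;
  cv.W = arma::conv_to<fmat>::from(as<arma::mat>(Wm));
  cv.b = arma::conv_to<frowvec>::from(as<arma::rowvec>(b));
  ConvUse u;
  fmat Y = conv_fwd(cv, u, X, 1, H, W, false);
  NumericVector out(Y.n_elem);
  for (uword i = 0; i < Y.n_elem; ++i) out[i] = Y[i];
  out.attr("dim") = IntegerVector::create(H, W, (int)Y.n_cols);
  return out;
}
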