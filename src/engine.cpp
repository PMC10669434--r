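// Minimal single-threaded CNN engine for the SRN family: stride-1 "same"
// convolutions via im2col + BLAS GEMM (single precision), ReLU, 2x2 stride-2
// floor max-pooling, global average pooling, a fully connected sigmoid head,
// multi-label binary cross-entropy, SGD with momentum and weight decay, and
// gradient capture at a block output for Grad-CAM. All state lives behind an
// external pointer; the engine itself holds no random number generator, so
// every computation is deterministic given parameters and inputs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::CharacterVector;
using Rcpp::XPtr;
using Rcpp::stop;

static inline void relu_inplace(fcube& x) {
  float* p = x.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// dY *= (act > 0): converts a gradient w.r.t. a post-ReLU activation into the
// gradient w.r.t. the pre-activation.
static inline void mask_relu(fcube& dy, const fcube& act) {
  float* d = dy.memptr();
  const float* a = act.memptr();
  const uword n = dy.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] <= 0.0f) d[i] = 0.0f;
}

// im2col for stride-1 "same" convolution. Input cube (H, W, C); output matrix
// (P x k*k*C) with P = H*W, position index p = h + w*H. Column index
// r = c*k*k + kj*k + ki maps to input offset (ki - pad, kj - pad). Only the
// padding fringe is zero-filled; the interior is copied column-segment-wise.
static void im2col(const fcube& x, int k, int pad, fmat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword P = (uword)H * W;
  col.set_size(P, (uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    const fmat& xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword r = (uword)c * k * k + (uword)kj * k + ki;
        float* dst = col.colptr(r);
        const int h0 = std::max(0, pad - ki), h1 = std::min(H, H + pad - ki);
        const int w0 = std::max(0, pad - kj), w1 = std::min(W, W + pad - kj);
        for (int w = 0; w < w0; ++w)
          std::memset(dst + (size_t)w * H, 0, sizeof(float) * H);
        for (int w = w0; w < w1; ++w) {
          float* d = dst + (size_t)w * H;
          if (h0 > 0) std::memset(d, 0, sizeof(float) * h0);
          std::memcpy(d + h0, xs.colptr(w + kj - pad) + (h0 + ki - pad),
                      sizeof(float) * (h1 - h0));
          if (h1 < H) std::memset(d + h1, 0, sizeof(float) * (H - h1));
        }
        for (int w = w1; w < W; ++w)
          std::memset(dst + (size_t)w * H, 0, sizeof(float) * H);
      }
    }
  }
}

// Scatter-add adjoint of im2col.
static void col2im(const fmat& dcol, int k, int pad, fcube& dx) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    fmat& xs = dx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword r = (uword)c * k * k + (uword)kj * k + ki;
        const float* src = dcol.colptr(r);
        const int h0 = std::max(0, pad - ki), h1 = std::min(H, H + pad - ki);
        const int w0 = std::max(0, pad - kj), w1 = std::min(W, W + pad - kj);
        for (int w = w0; w < w1; ++w) {
          float* dst = xs.colptr(w + kj - pad) + (h0 + ki - pad);
          const float* s = src + (size_t)w * H + h0;
          const int n = h1 - h0;
          for (int h = 0; h < n; ++h) dst[h] += s[h];
        }
      }
    }
  }
}

// 2x2 stride-2 max-pool, floor mode (odd trailing row/column dropped).
static void maxpool2(const fcube& x, fcube& y, umat& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  y.set_size(H2, W2, C);
  idx.set_size((uword)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const fmat& xs = x.slice(c);
    fmat& ys = y.slice(c);
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        const int bi = 2 * h, bj = 2 * w;
        float best = xs.at(bi, bj);
        uword bix = (uword)bi + (uword)bj * H;
        if (xs.at(bi + 1, bj) > best) { best = xs.at(bi + 1, bj); bix = (uword)(bi + 1) + (uword)bj * H; }
        if (xs.at(bi, bj + 1) > best) { best = xs.at(bi, bj + 1); bix = (uword)bi + (uword)(bj + 1) * H; }
        if (xs.at(bi + 1, bj + 1) > best) { best = xs.at(bi + 1, bj + 1); bix = (uword)(bi + 1) + (uword)(bj + 1) * H; }
        ys.at(h, w) = best;
        idx.at((uword)h + (uword)w * H2, c) = bix;
      }
    }
  }
}

static void unpool2(const fcube& dy, const umat& idx, int H, int W, fcube& dx) {
  dx.zeros(H, W, dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c) {
    const float* dp = dy.slice(c).memptr();
    float* xp = dx.slice(c).memptr();
    const uword n = dy.n_rows * dy.n_cols;
    for (uword p = 0; p < n; ++p) xp[idx.at(p, c)] += dp[p];
  }
}

struct ConvLayer {
  int k = 0, cin = 0, cout = 0, pad = 0;
  fmat W, gW, vW;        // (k*k*cin) x cout
  frowvec b, gb, vb;     // length cout
  fmat col, dcol;        // persistent im2col buffers; `col` filled by the
                         // forward pass and reused by the backward pass of
                         // the same image

  void init(int k_, int cin_, int cout_) {
    k = k_; cin = cin_; cout = cout_; pad = k_ / 2;
    const uword K = (uword)k * k * cin;
    W.zeros(K, cout); gW.zeros(K, cout); vW.zeros(K, cout);
    b.zeros(cout); gb.zeros(cout); vb.zeros(cout);
  }
  uword np() const { return W.n_elem + b.n_elem; }

  void forward(const fcube& x, fcube& y) {
    im2col(x, k, pad, col);
    const uword P = x.n_rows * x.n_cols;
    y.set_size(x.n_rows, x.n_cols, cout);
    fmat Ym(y.memptr(), P, cout, false, true);
    Ym = col * W;
    Ym.each_row() += b;
  }

  // Uses the `col` buffer of the matching forward pass.
  void backward(const fcube& dy, fcube& dx, bool want_dx) {
    const uword P = dy.n_rows * dy.n_cols;
    const fmat dYm(const_cast<float*>(dy.memptr()), P, cout, false, true);
    gW += col.t() * dYm;
    gb += sum(dYm, 0);
    if (want_dx) {
      dcol = dYm * W.t();
      dx.zeros(dy.n_rows, dy.n_cols, cin);
      col2im(dcol, k, pad, dx);
    }
  }

  void step(float lr, float mom, float wd) {
    vW = mom * vW + gW + wd * W;
    W -= lr * vW;
    vb = mom * vb + gb + wd * b;
    b -= lr * vb;
    gW.zeros(); gb.zeros();
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
};

struct Block {
  std::vector<ConvLayer> convs;
  bool residual = false, has_proj = false;
  ConvLayer proj;                 // 1x1 projection on the skip path
  // per-image caches (valid after forward(cache = true))
  std::vector<fcube> inter;       // inter[l] = post-ReLU output of conv l, l < L-1
  fcube out_act;                  // post-(skip-add)-ReLU map, pre-pool
  umat pidx;
  int pooledH = 0, pooledW = 0;

  uword np() const {
    uword s = 0;
    for (const auto& c : convs) s += c.np();
    if (has_proj) s += proj.np();
    return s;
  }
};

struct Trunk {
  int in_channels = 0, feat_dim = 0;
  std::vector<Block> blocks;

  fvec forward(const fcube& x, bool cache) {
    fcube cur = x;
    for (auto& B : blocks) {
      if (cache) B.inter.clear();
      const int L = (int)B.convs.size();
      fcube y;
      {
        const fcube* a = &cur;
        for (int l = 0; l < L; ++l) {
          B.convs[l].forward(*a, y);
          const bool relu_here = !(B.residual && l == L - 1);
          if (relu_here) relu_inplace(y);
          if (l < L - 1) {
            B.inter.push_back(std::move(y));
            a = &B.inter.back();
            y = fcube();
          }
        }
      }
      if (B.residual) {
        if (B.has_proj) {
          fcube s;
          B.proj.forward(cur, s);
          y += s;
        } else {
          y += cur;
        }
        relu_inplace(y);
      }
      fcube p; umat idx;
      maxpool2(y, p, idx);
      if (cache) {
        B.out_act = std::move(y);
        B.pidx = std::move(idx);
        B.pooledH = p.n_rows; B.pooledW = p.n_cols;
      }
      if (!cache) B.inter.clear();
      cur = std::move(p);
    }
    // global average pool
    fvec f(feat_dim);
    const float inv = 1.0f / (cur.n_rows * cur.n_cols);
    for (int c = 0; c < feat_dim; ++c) f[c] = accu(cur.slice(c)) * inv;
    return f;
  }

  // Backpropagates dfeat (gradient w.r.t. the pooled 512-feature) through the
  // cached forward pass, accumulating parameter gradients. When capture >= 0,
  // the post-ReLU activation of that block (pre-pool) and the gradient w.r.t.
  // it are copied out (Grad-CAM).
  void backward(const fvec& dfeat, int capture, fcube& cap_act, fcube& cap_grad) {
    Block& last = blocks.back();
    const int H = last.pooledH, W = last.pooledW;
    fcube dcur(H, W, (uword)feat_dim);
    const float inv = 1.0f / (H * W);
    for (int c = 0; c < feat_dim; ++c) dcur.slice(c).fill(dfeat[c] * inv);

    for (int b = (int)blocks.size() - 1; b >= 0; --b) {
      Block& B = blocks[b];
      fcube dY;
      unpool2(dcur, B.pidx, B.out_act.n_rows, B.out_act.n_cols, dY);
      if (b == capture) { cap_act = B.out_act; cap_grad = dY; }
      mask_relu(dY, B.out_act);
      fcube dskip;
      if (B.residual) {
        if (B.has_proj) B.proj.backward(dY, dskip, true);
        else dskip = dY;
      }
      const int L = (int)B.convs.size();
      fcube d = std::move(dY), dx;
      for (int l = L - 1; l >= 0; --l) {
        const bool want_dx = !(b == 0 && l == 0);
        B.convs[l].backward(d, dx, want_dx);
        if (l > 0) {
          mask_relu(dx, B.inter[l - 1]);
          d = std::move(dx);
        }
      }
      if (b == 0) break;
      dcur = std::move(dx);
      if (B.residual) dcur += dskip;
    }
  }

  void step(float lr, float mom, float wd) {
    for (auto& B : blocks) {
      for (auto& c : B.convs) c.step(lr, mom, wd);
      if (B.has_proj) B.proj.step(lr, mom, wd);
    }
  }
  void zero_grad() {
    for (auto& B : blocks) {
      for (auto& c : B.convs) c.zero_grad();
      if (B.has_proj) B.proj.zero_grad();
    }
  }
};

struct Net {
  std::vector<Trunk> branches;
  int C = 0, fin = 0;
  fmat Wh, gWh, vWh;    // fin x C
  frowvec bh, gbh, vbh; // length C
};

// ---------------------------------------------------------------------------
// construction / parameter plumbing
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(List plan) {
  const int in_channels = Rcpp::as<int>(plan["in_channels"]);
  const int num_classes = Rcpp::as<int>(plan["num_classes"]);
  List branches = plan["branches"];
  Net* net = new Net();
  net->C = num_classes;
  for (int br = 0; br < branches.size(); ++br) {
    List bp = branches[br];
    List blocks = bp["blocks"];
    Trunk tr;
    tr.in_channels = in_channels;
    int cin = in_channels;
    for (int bi = 0; bi < blocks.size(); ++bi) {
      List bs = blocks[bi];
      IntegerVector kernels = bs["kernels"];
      IntegerVector channels = bs["channels"];
      Block B;
      B.residual = Rcpp::as<bool>(bs["residual"]);
      const int block_in = cin;
      for (int l = 0; l < kernels.size(); ++l) {
        ConvLayer c;
        c.init(kernels[l], cin, channels[l]);
        cin = channels[l];
        B.convs.push_back(std::move(c));
      }
      if (B.residual && block_in != cin) {
        B.has_proj = true;
        B.proj.init(1, block_in, cin);
      }
      tr.blocks.push_back(std::move(B));
    }
    tr.feat_dim = cin;
    net->branches.push_back(std::move(tr));
  }
  for (const auto& t : net->branches) net->fin += t.feat_dim;
  net->Wh.zeros(net->fin, net->C);
  net->gWh.zeros(net->fin, net->C);
  net->vWh.zeros(net->fin, net->C);
  net->bh.zeros(net->C); net->gbh.zeros(net->C); net->vbh.zeros(net->C);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// Tensor-by-tensor layout of the flat parameter vector (1-based offsets).
// [[Rcpp::export(name = ".net_param_layout")]]
Rcpp::DataFrame net_param_layout(SEXP ptr_) {
  XPtr<Net> net(ptr_);
  std::vector<std::string> names;
  std::vector<double> offsets, sizes;
  double off = 1;
  auto add = [&](const std::string& nm, uword n) {
    names.push_back(nm); offsets.push_back(off); sizes.push_back((double)n);
    off += n;
  };
  for (size_t br = 0; br < net->branches.size(); ++br) {
    const Trunk& t = net->branches[br];
    for (size_t b = 0; b < t.blocks.size(); ++b) {
      const Block& B = t.blocks[b];
      const std::string pre = "branch" + std::to_string(br + 1) + ".block" + std::to_string(b + 1);
      for (size_t l = 0; l < B.convs.size(); ++l) {
        add(pre + ".conv" + std::to_string(l + 1) + ".weight", B.convs[l].W.n_elem);
        add(pre + ".conv" + std::to_string(l + 1) + ".bias", B.convs[l].b.n_elem);
      }
      if (B.has_proj) {
        add(pre + ".proj.weight", B.proj.W.n_elem);
        add(pre + ".proj.bias", B.proj.b.n_elem);
      }
    }
  }
  add("head.weight", net->Wh.n_elem);
  add("head.bias", net->bh.n_elem);
  return Rcpp::DataFrame::create(Rcpp::Named("tensor") = names,
                                 Rcpp::Named("offset") = offsets,
                                 Rcpp::Named("size") = sizes);
}

// [[Rcpp::export(name = ".net_nparams")]]
double net_nparams(SEXP ptr_) {
  XPtr<Net> net(ptr_);
  uword n = net->Wh.n_elem + net->bh.n_elem;
  for (const auto& t : net->branches)
    for (const auto& B : t.blocks) n += B.np();
  return (double)n;
}

// [[Rcpp::export(name = ".net_get_params")]]
NumericVector net_get_params(SEXP ptr_) {
  XPtr<Net> net(ptr_);
  NumericVector out((R_xlen_t)net_nparams(ptr_));
  R_xlen_t i = 0;
  auto putm = [&](const fmat& M) { for (uword j = 0; j < M.n_elem; ++j) out[i++] = M.memptr()[j]; };
  auto putv = [&](const frowvec& v) { for (uword j = 0; j < v.n_elem; ++j) out[i++] = v[j]; };
  for (auto& t : net->branches)
    for (auto& B : t.blocks) {
      for (auto& c : B.convs) { putm(c.W); putv(c.b); }
      if (B.has_proj) { putm(B.proj.W); putv(B.proj.b); }
    }
  putm(net->Wh); putv(net->bh);
  return out;
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP ptr_, NumericVector v) {
  XPtr<Net> net(ptr_);
  if ((double)v.size() != net_nparams(ptr_)) stop("parameter vector has wrong length");
  R_xlen_t i = 0;
  auto getm = [&](fmat& M) { for (uword j = 0; j < M.n_elem; ++j) M.memptr()[j] = (float)v[i++]; };
  auto getv = [&](frowvec& w) { for (uword j = 0; j < w.n_elem; ++j) w[j] = (float)v[i++]; };
  for (auto& t : net->branches)
    for (auto& B : t.blocks) {
      for (auto& c : B.convs) { getm(c.W); getv(c.b); }
      if (B.has_proj) { getm(B.proj.W); getv(B.proj.b); }
    }
  getm(net->Wh); getv(net->bh);
}

// [[Rcpp::export(name = ".net_reset_momentum")]]
void net_reset_momentum(SEXP ptr_) {
  XPtr<Net> net(ptr_);
  for (auto& t : net->branches)
    for (auto& B : t.blocks) {
      for (auto& c : B.convs) { c.vW.zeros(); c.vb.zeros(); }
      if (B.has_proj) { B.proj.vW.zeros(); B.proj.vb.zeros(); }
    }
  net->vWh.zeros(); net->vbh.zeros();
}

// ---------------------------------------------------------------------------
// forward / training
// ---------------------------------------------------------------------------

// xs: list with one numeric array (H, W, cin, N) per branch.
static fcube image_cube(const NumericVector& arr, const IntegerVector& dim, int i) {
  const int H = dim[0], W = dim[1], C = dim[2];
  fcube x(H, W, C);
  const double* src = arr.begin() + (size_t)H * W * C * i;
  float* dst = x.memptr();
  const size_t n = (size_t)H * W * C;
  for (size_t j = 0; j < n; ++j) dst[j] = (float)src[j];
  return x;
}

static void head_forward(const Net* net, const fvec& f, fvec& logits, fvec& probs) {
  logits = net->Wh.t() * f + net->bh.t();
  probs = 1.0f / (1.0f + exp(-logits));
}

// [[Rcpp::export(name = ".net_forward")]]
List net_forward(SEXP ptr_, List xs) {
  XPtr<Net> net(ptr_);
  const int B = (int)net->branches.size();
  if (xs.size() != B) stop("expected %d branch inputs", B);
  std::vector<NumericVector> arrs;
  std::vector<IntegerVector> dims;
  int N = -1;
  for (int br = 0; br < B; ++br) {
    NumericVector a(xs[br]);
    IntegerVector d = a.attr("dim");
    if (d.size() != 4) stop("branch input must be a 4-d array (H, W, C, N)");
    if (N < 0) N = d[3];
    else if (d[3] != N) stop("branch inputs disagree on batch size");
    arrs.push_back(a); dims.push_back(d);
  }
  NumericMatrix feat(N, net->fin), prob(N, net->C);
  for (int i = 0; i < N; ++i) {
    fvec f(net->fin);
    int off = 0;
    for (int br = 0; br < B; ++br) {
      fcube x = image_cube(arrs[br], dims[br], i);
      fvec fb = net->branches[br].forward(x, false);
      f.subvec(off, off + net->branches[br].feat_dim - 1) = fb;
      off += net->branches[br].feat_dim;
    }
    fvec logits, p;
    head_forward(net, f, logits, p);
    for (int c = 0; c < net->fin; ++c) feat(i, c) = f[c];
    for (int c = 0; c < net->C; ++c) prob(i, c) = p[c];
  }
  return List::create(Rcpp::Named("features") = feat, Rcpp::Named("probabilities") = prob);
}

// One SGD mini-batch: per-image forward/backward (interleaved so activation
// caches are reused image by image), then a single parameter update. Returns
// the clamped multi-label BCE loss averaged over the batch.
// [[Rcpp::export(name = ".net_train_batch")]]
double net_train_batch(SEXP ptr_, List xs, NumericMatrix y, double lr,
                       double momentum, double weight_decay, double eps) {
  XPtr<Net> net(ptr_);
  const int B = (int)net->branches.size();
  if (xs.size() != B) stop("expected %d branch inputs", B);
  std::vector<NumericVector> arrs;
  std::vector<IntegerVector> dims;
  int N = -1;
  for (int br = 0; br < B; ++br) {
    NumericVector a(xs[br]);
    IntegerVector d = a.attr("dim");
    if (N < 0) N = d[3];
    else if (d[3] != N) stop("branch inputs disagree on batch size");
    arrs.push_back(a); dims.push_back(d);
  }
  if (y.nrow() != N || y.ncol() != net->C) stop("label matrix has wrong shape");

  const float scale = 1.0f / ((float)N * net->C);
  double loss = 0.0;
  fcube dummy_a, dummy_g;
  for (int i = 0; i < N; ++i) {
    fvec f(net->fin);
    int off = 0;
    for (int br = 0; br < B; ++br) {
      fcube x = image_cube(arrs[br], dims[br], i);
      fvec fb = net->branches[br].forward(x, true);
      f.subvec(off, off + net->branches[br].feat_dim - 1) = fb;
      off += net->branches[br].feat_dim;
    }
    fvec logits, p;
    head_forward(net, f, logits, p);
    fvec dlogit(net->C);
    for (int c = 0; c < net->C; ++c) {
      const double yy = y(i, c);
      double pc = p[c];
      if (pc < eps) pc = eps;
      if (pc > 1.0 - eps) pc = 1.0 - eps;
      loss += -(yy * std::log(pc) + (1.0 - yy) * std::log(1.0 - pc));
      dlogit[c] = (float)((p[c] - yy)) * scale;
    }
    net->gWh += f * dlogit.t();
    net->gbh += dlogit.t();
    fvec dfeat = net->Wh * dlogit;
    off = 0;
    for (int br = 0; br < B; ++br) {
      const int fd = net->branches[br].feat_dim;
      fvec dfb = dfeat.subvec(off, off + fd - 1);
      net->branches[br].backward(dfb, -1, dummy_a, dummy_g);
      off += fd;
    }
  }
  if (!std::isfinite(loss)) stop("non-finite training loss (divergence)");
  const float lrf = (float)lr, momf = (float)momentum, wdf = (float)weight_decay;
  for (auto& t : net->branches) t.step(lrf, momf, wdf);
  net->vWh = momf * net->vWh + net->gWh + wdf * net->Wh;
  net->Wh -= lrf * net->vWh;
  net->vbh = momf * net->vbh + net->gbh + wdf * net->bh;
  net->bh -= lrf * net->vbh;
  net->gWh.zeros(); net->gbh.zeros();
  return loss / ((double)N * net->C);
}

// Grad-CAM raw material: activations of one block's output map (post-ReLU,
// pre-pool) and the gradient of one class logit w.r.t. that map, for a single
// image on a single branch.
// [[Rcpp::export(name = ".net_gradcam")]]
List net_gradcam(SEXP ptr_, NumericVector x, int branch, int block, int class_index) {
  XPtr<Net> net(ptr_);
  if (branch < 1 || branch > (int)net->branches.size()) stop("invalid branch index");
  Trunk& tr = net->branches[branch - 1];
  if (block < 1 || block > (int)tr.blocks.size()) stop("invalid block index");
  if (class_index < 1 || class_index > net->C) stop("invalid class index");
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("image must be a 3-d array (H, W, C)");
  fcube xc(d[0], d[1], d[2]);
  for (uword j = 0; j < xc.n_elem; ++j) xc.memptr()[j] = (float)x[j];

  tr.forward(xc, true);
  // gradient of the class logit w.r.t. this branch's feature slice
  int off = 0;
  for (int br = 0; br < branch - 1; ++br) off += net->branches[br].feat_dim;
  fvec dfeat = net->Wh.col(class_index - 1).subvec(off, off + tr.feat_dim - 1);
  fcube act, grad;
  tr.backward(dfeat, block - 1, act, grad);
  tr.zero_grad();  // gradients were accumulated but must not leak into training

  Rcpp::NumericVector av(act.n_elem), gv(grad.n_elem);
  for (uword j = 0; j < act.n_elem; ++j) av[j] = act.memptr()[j];
  for (uword j = 0; j < grad.n_elem; ++j) gv[j] = grad.memptr()[j];
  av.attr("dim") = IntegerVector::create(act.n_rows, act.n_cols, act.n_slices);
  gv.attr("dim") = IntegerVector::create(grad.n_rows, grad.n_cols, grad.n_slices);
  return List::create(Rcpp::Named("activations") = av, Rcpp::Named("gradients") = gv);
}

// ---------------------------------------------------------------------------
// small image-geometry helpers (bilinear, deterministic)
// ---------------------------------------------------------------------------

static inline double sample_bilinear(const NumericMatrix& img, double si, double sj,
                                     double bg) {
  const int H = img.nrow(), W = img.ncol();
  if (si < -1.0 || si > (double)H || sj < -1.0 || sj > (double)W) return bg;
  const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
  const double fi = si - i0, fj = sj - j0;
  auto at = [&](int i, int j) -> double {
    if (i < 0 || i >= H || j < 0 || j >= W) return bg;
    return img(i, j);
  };
  return (1 - fi) * ((1 - fj) * at(i0, j0) + fj * at(i0, j0 + 1)) +
         fi * ((1 - fj) * at(i0 + 1, j0) + fj * at(i0 + 1, j0 + 1));
}

// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix img, int oh, int ow) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  const double si_scale = (double)H / oh, sj_scale = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    const double sj = (j + 0.5) * sj_scale - 0.5;
    for (int i = 0; i < oh; ++i) {
      const double si = (i + 0.5) * si_scale - 0.5;
      double cii = si < 0 ? 0 : (si > H - 1 ? H - 1 : si);
      double cjj = sj < 0 ? 0 : (sj > W - 1 ? W - 1 : sj);
      out(i, j) = sample_bilinear(img, cii, cjj, 0.0);
    }
  }
  return out;
}

// Rotation about the image centre by `degrees` (counter-clockwise), bilinear
// resampling, out-of-frame pixels filled with `bg`.
// [[Rcpp::export(name = ".rotate_bilinear")]]
NumericMatrix rotate_bilinear(NumericMatrix img, double degrees, double bg) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = degrees * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double di = i - ci, dj = j - cj;
      const double si = c * di - s * dj + ci;   // inverse rotation
      const double sj = s * di + c * dj + cj;
      out(i, j) = sample_bilinear(img, si, sj, bg);
    }
  }
  return out;
}
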