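// Compact nested-skip (UNet++-style, depth 2) semantic segmentation network
// with residual encoder blocks, trained by backpropagation with Adam on a
// summed cross-entropy + soft-Dice loss. Feature maps are stored as
// (channels x H*W) single-precision matrices with spatial index r*W + c;
// 3x3 convolutions are computed as 9 shifted GEMMs (no im2col buffer), which
// bounds memory at slide-scale patch sizes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Conv {
  int cin, cout, k;       // k = 1 or 3
  fmat W;                 // cout x (k*k*cin)
  fvec b;                 // cout
  fmat gW; fvec gb;       // gradients
  fmat mW, vW; fvec mb, vb;  // Adam state

  void alloc(int cin_, int cout_, int k_) {
    cin = cin_; cout = cout_; k = k_;
    W.zeros(cout, k * k * cin); b.zeros(cout);
    gW.zeros(arma::size(W)); gb.zeros(cout);
    mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    mb.zeros(cout); vb.zeros(cout);
  }
  void init() {
    const double sd = std::sqrt(2.0 / (k * k * cin));
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = (float)(sd * norm_rand());
    b.zeros();
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
};

static const int OFF[9][2] = {
  {-1,-1},{-1,0},{-1,1},{0,-1},{0,0},{0,1},{1,-1},{1,0},{1,1}
};

// Y = conv(X) with 'same' zero padding.
static fmat conv_fwd(const Conv &cv, const fmat &X, int H, int W) {
  fmat Y(cv.cout, (arma::uword)H * W);
  Y.each_col() = cv.b;
  if (cv.k == 1) {
    Y += cv.W * X;
    return Y;
  }
  for (int kk = 0; kk < 9; ++kk) {
    const int dy = OFF[kk][0], dx = OFF[kk][1];
    const fmat Wk = cv.W.cols(kk * cv.cin, (kk + 1) * cv.cin - 1);
    const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
    if (c0 > c1) continue;
    for (int r = 0; r < H; ++r) {
      const int ri = r + dy;
      if (ri < 0 || ri >= H) continue;
      Y.cols((arma::uword)r * W + c0, (arma::uword)r * W + c1) +=
        Wk * X.cols((arma::uword)ri * W + c0 + dx, (arma::uword)ri * W + c1 + dx);
    }
  }
  return Y;
}

// Accumulates cv.gW / cv.gb and returns dX.
static fmat conv_bwd(Conv &cv, const fmat &X, const fmat &dY, int H, int W) {
  cv.gb += arma::sum(dY, 1);
  fmat dX(cv.cin, (arma::uword)H * W, arma::fill::zeros);
  if (cv.k == 1) {
    cv.gW += dY * X.t();
    dX = cv.W.t() * dY;
    return dX;
  }
  for (int kk = 0; kk < 9; ++kk) {
    const int dy = OFF[kk][0], dx = OFF[kk][1];
    const fmat Wk = cv.W.cols(kk * cv.cin, (kk + 1) * cv.cin - 1);
    fmat gWk(cv.cout, cv.cin, arma::fill::zeros);
    const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
    if (c0 > c1) continue;
    for (int r = 0; r < H; ++r) {
      const int ri = r + dy;
      if (ri < 0 || ri >= H) continue;
      const auto dYs = dY.cols((arma::uword)r * W + c0, (arma::uword)r * W + c1);
      const auto Xs  = X.cols((arma::uword)ri * W + c0 + dx, (arma::uword)ri * W + c1 + dx);
      gWk += dYs * Xs.t();
      dX.cols((arma::uword)ri * W + c0 + dx, (arma::uword)ri * W + c1 + dx) += Wk.t() * dYs;
    }
    cv.gW.cols(kk * cv.cin, (kk + 1) * cv.cin - 1) += gWk;
  }
  return dX;
}

// Residual block: y = relu(convB(relu(convA(x))) + proj(x))
struct Block {
  Conv a, b, p;
  void alloc(int cin, int cout) {
    a.alloc(cin, cout, 3); b.alloc(cout, cout, 3); p.alloc(cin, cout, 1);
  }
  void init() { a.init(); b.init(); p.init(); }
  void zero_grad() { a.zero_grad(); b.zero_grad(); p.zero_grad(); }
};

struct BlockCache { fmat X, R1, Y; int H, W; };

static fmat block_fwd(Block &bl, const fmat &X, int H, int W, BlockCache *cache) {
  fmat A1 = conv_fwd(bl.a, X, H, W);
  A1.transform([](float v) { return v > 0 ? v : 0.0f; });
  fmat S = conv_fwd(bl.b, A1, H, W) + conv_fwd(bl.p, X, H, W);
  S.transform([](float v) { return v > 0 ? v : 0.0f; });
  if (cache) { cache->X = X; cache->R1 = std::move(A1); cache->H = H; cache->W = W; cache->Y = S; }
  return S;
}

static fmat block_bwd(Block &bl, const BlockCache &cc, fmat dY) {
  dY.elem(arma::find(cc.Y <= 0)).zeros();
  fmat dX = conv_bwd(bl.p, cc.X, dY, cc.H, cc.W);
  fmat dR1 = conv_bwd(bl.b, cc.R1, dY, cc.H, cc.W);
  dR1.elem(arma::find(cc.R1 <= 0)).zeros();
  dX += conv_bwd(bl.a, cc.X, dR1, cc.H, cc.W);
  return dX;
}

static fmat maxpool_fwd(const fmat &X, int H, int W, arma::umat *argmax) {
  const int Ho = H / 2, Wo = W / 2, C = X.n_rows;
  fmat Y(C, (arma::uword)Ho * Wo);
  if (argmax) argmax->set_size(C, (arma::uword)Ho * Wo);
  for (int r = 0; r < Ho; ++r) {
    for (int c = 0; c < Wo; ++c) {
      const arma::uword o = (arma::uword)r * Wo + c;
      const arma::uword i00 = (arma::uword)(2 * r) * W + 2 * c;
      const arma::uword idx[4] = {i00, i00 + 1, i00 + W, i00 + W + 1};
      for (int ch = 0; ch < C; ++ch) {
        float best = X(ch, idx[0]); arma::uword bi = idx[0];
        for (int t = 1; t < 4; ++t)
          if (X(ch, idx[t]) > best) { best = X(ch, idx[t]); bi = idx[t]; }
        Y(ch, o) = best;
        if (argmax) (*argmax)(ch, o) = bi;
      }
    }
  }
  return Y;
}

static fmat maxpool_bwd(const fmat &dY, const arma::umat &argmax, int H, int W) {
  fmat dX(dY.n_rows, (arma::uword)H * W, arma::fill::zeros);
  for (arma::uword o = 0; o < dY.n_cols; ++o)
    for (arma::uword ch = 0; ch < dY.n_rows; ++ch)
      dX(ch, argmax(ch, o)) += dY(ch, o);
  return dX;
}

static fmat upsample_fwd(const fmat &X, int H, int W) {  // H, W of input
  const int C = X.n_rows, Ho = 2 * H, Wo = 2 * W;
  fmat Y(C, (arma::uword)Ho * Wo);
  for (int r = 0; r < Ho; ++r)
    for (int c = 0; c < Wo; ++c)
      Y.col((arma::uword)r * Wo + c) = X.col((arma::uword)(r / 2) * W + c / 2);
  return Y;
}

static fmat upsample_bwd(const fmat &dY, int H, int W) {  // H, W of input
  const int C = dY.n_rows, Wo = 2 * W;
  fmat dX(C, (arma::uword)H * W, arma::fill::zeros);
  for (int r = 0; r < 2 * H; ++r)
    for (int c = 0; c < Wo; ++c)
      dX.col((arma::uword)(r / 2) * W + c / 2) += dY.col((arma::uword)r * Wo + c);
  return dX;
}

struct Net {
  int base, nclass, inch;
  Block enc0, enc1, enc2, dec01, dec11, dec02;
  Conv head;
  long adam_t = 0;

  Net(int base_, int nclass_, int inch_ = 3) : base(base_), nclass(nclass_), inch(inch_) {
    const int c = base;
    enc0.alloc(inch, c);
    enc1.alloc(c, 2 * c);
    enc2.alloc(2 * c, 4 * c);
    dec01.alloc(c + 2 * c, c);
    dec11.alloc(2 * c + 4 * c, 2 * c);
    dec02.alloc(c + c + 2 * c, c);
    head.alloc(c, nclass, 1);
  }

  std::vector<Conv *> convs() {
    return {&enc0.a, &enc0.b, &enc0.p, &enc1.a, &enc1.b, &enc1.p,
            &enc2.a, &enc2.b, &enc2.p, &dec01.a, &dec01.b, &dec01.p,
            &dec11.a, &dec11.b, &dec11.p, &dec02.a, &dec02.b, &dec02.p, &head};
  }
  void init() { for (auto cv : convs()) cv->init(); adam_t = 0; }
  void zero_grad() { for (auto cv : convs()) cv->zero_grad(); }

  void adam_step(double lr) {
    ++adam_t;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const double corr = lr * std::sqrt(1 - std::pow(b2, (double)adam_t)) /
                        (1 - std::pow(b1, (double)adam_t));
    for (auto cv : convs()) {
      cv->mW = (float)b1 * cv->mW + (float)(1 - b1) * cv->gW;
      cv->vW = (float)b2 * cv->vW + (float)(1 - b2) * arma::square(cv->gW);
      cv->W -= (float)corr * cv->mW / (arma::sqrt(cv->vW) + (float)eps);
      cv->mb = (float)b1 * cv->mb + (float)(1 - b1) * cv->gb;
      cv->vb = (float)b2 * cv->vb + (float)(1 - b2) * arma::square(cv->gb);
      cv->b -= (float)corr * cv->mb / (arma::sqrt(cv->vb) + (float)eps);
    }
  }
};

struct NetCache {
  BlockCache e0, e1, e2, d01, d11, d02;
  arma::umat am0, am1;
  fmat x00, x10, x20, x01, x11, in01, in11, in02;
  int H, W;
};

// Forward pass; fills cache when given (training).
static fmat net_forward_impl(Net &net, const fmat &img, int H, int W, NetCache *cc) {
  BlockCache tmp;
  NetCache local;
  NetCache &C = cc ? *cc : local;
  C.H = H; C.W = W;
  fmat x00 = block_fwd(net.enc0, img, H, W, cc ? &C.e0 : nullptr);
  fmat p0 = maxpool_fwd(x00, H, W, cc ? &C.am0 : nullptr);
  const int H1 = H / 2, W1 = W / 2;
  fmat x10 = block_fwd(net.enc1, p0, H1, W1, cc ? &C.e1 : nullptr);
  fmat p1 = maxpool_fwd(x10, H1, W1, cc ? &C.am1 : nullptr);
  const int H2 = H1 / 2, W2 = W1 / 2;
  fmat x20 = block_fwd(net.enc2, p1, H2, W2, cc ? &C.e2 : nullptr);

  fmat in01 = arma::join_cols(x00, upsample_fwd(x10, H1, W1));
  fmat x01 = block_fwd(net.dec01, in01, H, W, cc ? &C.d01 : nullptr);
  fmat in11 = arma::join_cols(x10, upsample_fwd(x20, H2, W2));
  fmat x11 = block_fwd(net.dec11, in11, H1, W1, cc ? &C.d11 : nullptr);
  fmat in02 = arma::join_cols(arma::join_cols(x00, x01), upsample_fwd(x11, H1, W1));
  fmat x02 = block_fwd(net.dec02, in02, H, W, cc ? &C.d02 : nullptr);
  fmat logits = conv_fwd(net.head, x02, H, W);
  if (cc) {
    C.x00 = std::move(x00); C.x10 = std::move(x10); C.x20 = std::move(x20);
    C.x01 = std::move(x01); C.x11 = std::move(x11);
    C.in01 = std::move(in01); C.in11 = std::move(in11); C.in02 = std::move(in02);
  }
  return logits;
}

static void net_backward_impl(Net &net, NetCache &C, const fmat &dlogits) {
  const int H = C.H, W = C.W, H1 = H / 2, W1 = W / 2, H2 = H1 / 2, W2 = W1 / 2;
  const int c = net.base;
  fmat dx02 = conv_bwd(net.head, C.d02.Y, dlogits, H, W);
  fmat din02 = block_bwd(net.dec02, C.d02, dx02);
  fmat dx00 = din02.rows(0, c - 1);
  fmat dx01 = din02.rows(c, 2 * c - 1);
  fmat dx11 = upsample_bwd(din02.rows(2 * c, 4 * c - 1), H1, W1);

  fmat din01 = block_bwd(net.dec01, C.d01, dx01);
  dx00 += din01.rows(0, c - 1);
  fmat dx10 = upsample_bwd(din01.rows(c, 3 * c - 1), H1, W1);

  fmat din11 = block_bwd(net.dec11, C.d11, dx11);
  dx10 += din11.rows(0, 2 * c - 1);
  fmat dx20 = upsample_bwd(din11.rows(2 * c, 6 * c - 1), H2, W2);

  fmat dp1 = block_bwd(net.enc2, C.e2, dx20);
  dx10 += maxpool_bwd(dp1, C.am1, H1, W1);
  fmat dp0 = block_bwd(net.enc1, C.e1, dx10);
  dx00 += maxpool_bwd(dp0, C.am0, H, W);
  block_bwd(net.enc0, C.e0, dx00);  // gradient w.r.t. input discarded
}

// Softmax over rows (classes) per column; in place.
static void softmax_cols(fmat &L) {
  for (arma::uword j = 0; j < L.n_cols; ++j) {
    fvec col = L.col(j);
    col -= col.max();
    col = arma::exp(col);
    L.col(j) = col / arma::accu(col);
  }
}

// Loss and (optionally) dlogits. target is 0-based class per pixel, spatial
// index r*W+c. Returns (ce, dice_loss).
static std::pair<double, double> loss_and_grad(const fmat &logits,
                                               const arma::ivec &target,
                                               int nclass, fmat *dlogits) {
  const arma::uword N = logits.n_cols;
  fmat P = logits;
  softmax_cols(P);
  double ce = 0;
  for (arma::uword j = 0; j < N; ++j)
    ce -= std::log(std::max(1e-12f, P(target(j), j)));
  ce /= (double)N;

  // soft Dice over non-background classes present in the target
  std::vector<int> cls;
  std::vector<double> I(nclass, 0), Sp(nclass, 0), St(nclass, 0);
  for (int k = 1; k < nclass; ++k) {
    double i = 0, sp = 0, st = 0;
    for (arma::uword j = 0; j < N; ++j) {
      const double p = P(k, j);
      sp += p;
      if (target(j) == k) { st += 1; i += p; }
    }
    if (st > 0) { cls.push_back(k); I[k] = i; Sp[k] = sp; St[k] = st; }
  }
  double dice = 0;
  if (!cls.empty()) {
    for (int k : cls) dice += 1.0 - 2.0 * I[k] / (Sp[k] + St[k]);
    dice /= cls.size();
  }

  if (dlogits) {
    // G = dLoss/dP
    fmat G(P.n_rows, N, arma::fill::zeros);
    for (arma::uword j = 0; j < N; ++j)
      G(target(j), j) = -1.0f / (float)(N * std::max(1e-12f, P(target(j), j)));
    if (!cls.empty()) {
      for (int k : cls) {
        const double S = Sp[k] + St[k];
        for (arma::uword j = 0; j < N; ++j) {
          const double t = (target(j) == k) ? 1.0 : 0.0;
          G(k, j) += (float)(-(2.0 / cls.size()) * (t * S - I[k]) / (S * S));
        }
      }
    }
    // chain through softmax: dL/dz_j = P_j * (G_j - sum_k G_k P_k)
    arma::frowvec dot = arma::sum(G % P, 0);
    *dlogits = P % (G.each_row() - dot);
  }
  return {ce, dice};
}

static fmat r_image_to_fmat(const NumericVector &img, int &H, int &W) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("image must be an H x W x C array");
  H = d[0]; W = d[1];
  const int C = d[2];
  fmat X(C, (arma::uword)H * W);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        X(ch, (arma::uword)r * W + c) =
          (float)img[(arma::uword)r + (arma::uword)H * c + (arma::uword)H * W * ch];
  return X;
}

static arma::ivec r_mask_to_target(const IntegerMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  arma::ivec t((arma::uword)H * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      t((arma::uword)r * W + c) = mask(r, c);
  return t;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(int base_channels, int n_classes, int in_channels = 3) {
  XPtr<Net> p(new Net(base_channels, n_classes, in_channels), true);
  return p;
}

// [[Rcpp::export(name = ".net_init")]]
void net_init(SEXP ptr) {
  XPtr<Net> net(ptr);
  net->init();
}

// [[Rcpp::export(name = ".net_nparams")]]
double net_nparams(SEXP ptr) {
  XPtr<Net> net(ptr);
  double n = 0;
  for (auto cv : net->convs()) n += cv->W.n_elem + cv->b.n_elem;
  return n;
}

// [[Rcpp::export(name = ".net_get_params")]]
NumericVector net_get_params(SEXP ptr) {
  XPtr<Net> net(ptr);
  std::vector<double> out;
  for (auto cv : net->convs()) {
    for (arma::uword i = 0; i < cv->W.n_elem; ++i) out.push_back(cv->W(i));
    for (arma::uword i = 0; i < cv->b.n_elem; ++i) out.push_back(cv->b(i));
  }
  return wrap(out);
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP ptr, NumericVector params) {
  XPtr<Net> net(ptr);
  arma::uword k = 0;
  for (auto cv : net->convs()) {
    if (k + cv->W.n_elem + cv->b.n_elem > (arma::uword)params.size())
      stop("parameter vector too short for this architecture");
    for (arma::uword i = 0; i < cv->W.n_elem; ++i) cv->W(i) = (float)params[k++];
    for (arma::uword i = 0; i < cv->b.n_elem; ++i) cv->b(i) = (float)params[k++];
  }
  if (k != (arma::uword)params.size())
    stop("parameter vector length does not match this architecture");
}

// [[Rcpp::export(name = ".net_forward")]]
NumericVector net_forward(SEXP ptr, NumericVector image) {
  XPtr<Net> net(ptr);
  int H, W;
  fmat X = r_image_to_fmat(image, H, W);
  if ((int)X.n_rows != net->inch) stop("image channel count does not match the network");
  if (H % 4 != 0 || W % 4 != 0) stop("patch height and width must be divisible by 4");
  fmat L = net_forward_impl(*net, X, H, W, nullptr);
  NumericVector out((arma::uword)H * W * net->nclass);
  out.attr("dim") = IntegerVector::create(H, W, net->nclass);
  for (int k = 0; k < net->nclass; ++k)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        out[(arma::uword)r + (arma::uword)H * c + (arma::uword)H * W * k] =
          L(k, (arma::uword)r * W + c);
  return out;
}

// [[Rcpp::export(name = ".net_train_batch")]]
List net_train_batch(SEXP ptr, List images, List masks, double lr) {
  XPtr<Net> net(ptr);
  const int B = images.size();
  if (B == 0 || masks.size() != B) stop("empty batch or image/mask count mismatch");
  net->zero_grad();
  double ce = 0, dice = 0;
  for (int b = 0; b < B; ++b) {
    int H, W;
    fmat X = r_image_to_fmat(images[b], H, W);
    if (H % 4 != 0 || W % 4 != 0) stop("patch height and width must be divisible by 4");
    arma::ivec t = r_mask_to_target(masks[b]);
    for (arma::uword j = 0; j < t.n_elem; ++j)
      if (t(j) < 0 || t(j) >= net->nclass) stop("target class outside the class map");
    NetCache cache;
    fmat L = net_forward_impl(*net, X, H, W, &cache);
    fmat dL;
    auto l = loss_and_grad(L, t, net->nclass, &dL);
    ce += l.first; dice += l.second;
    net_backward_impl(*net, cache, dL);
  }
  for (auto cv : net->convs()) { cv->gW /= (float)B; cv->gb /= (float)B; }
  if (!std::isfinite(ce + dice)) stop("non-finite loss (divergence)");
  net->adam_step(lr);
  return List::create(_["ce"] = ce / B, _["dice"] = dice / B,
                      _["loss"] = (ce + dice) / B);
}

// [[Rcpp::export(name = ".net_eval_loss")]]
List net_eval_loss(SEXP ptr, NumericVector image, IntegerMatrix mask) {
  XPtr<Net> net(ptr);
  int H, W;
  fmat X = r_image_to_fmat(image, H, W);
  if (H % 4 != 0 || W % 4 != 0) stop("patch height and width must be divisible by 4");
  arma::ivec t = r_mask_to_target(mask);
  fmat L = net_forward_impl(*net, X, H, W, nullptr);
  auto l = loss_and_grad(L, t, net->nclass, nullptr);
  return List::create(_["ce"] = l.first, _["dice"] = l.second,
                      _["loss"] = l.first + l.second);
}
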