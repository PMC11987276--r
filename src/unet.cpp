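// Small configurable-depth U-Net (encoder/decoder) for vessel segmentation,
// trained with the soft Tversky loss. Dense layers are expressed as GEMMs via
// im2col so the heavy lifting goes through BLAS. All state (weights, Adam
// moments) lives in flat R numeric vectors so models serialise as plain text.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace arma;

namespace {

// single precision throughout the network: CNN training does not need
// doubles, and the skinny GEMMs involved are memory-bound
typedef arma::fmat mat;
typedef arma::fvec vec;

// flush denormals: saturated sigmoids otherwise litter the tensors with
// subnormals, which are pathologically slow on x86
inline void set_ftz() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

// Feature maps: rows = channels, cols = H*W pixels, pixel index p = r + c*H
// (column-major, matching R's matrix vectorisation).

struct ConvSpec {
  int cin, cout, k; // k = 3 or 1
};

// Layer order for depth D (D resolution levels, D-1 poolings):
//  enc level l (l = 0..D-1): conv3(cin,c_l), conv3(c_l,c_l)   [level D-1 = bottleneck]
//  dec level l (l = D-2..0): conv3(c_{l+1},c_l) after nearest-up,
//                            conv3(2*c_l,c_l), conv3(c_l,c_l)
//  out: conv1(c_0, 1)
std::vector<ConvSpec> layer_specs(int depth, int base) {
  std::vector<ConvSpec> sp;
  int cin = 1;
  for (int l = 0; l < depth; ++l) {
    int c = base << l;
    sp.push_back({cin, c, 3});
    sp.push_back({c, c, 3});
    cin = c;
  }
  for (int l = depth - 2; l >= 0; --l) {
    int c = base << l;
    sp.push_back({c * 2, c, 3}); // up-conv after nearest-neighbour upsample
    sp.push_back({c * 2, c, 3}); // after concat with skip
    sp.push_back({c, c, 3});
  }
  sp.push_back({base, 1, 1});
  return sp;
}

long n_params(const std::vector<ConvSpec>& sp) {
  long n = 0;
  for (const auto& s : sp) n += (long)s.cout * s.cin * s.k * s.k + s.cout;
  return n;
}

struct Net {
  std::vector<ConvSpec> spec;
  std::vector<mat> W;  // cout x (cin*k*k)
  std::vector<vec> b;
  int depth, base;

  void from_flat(const vec& theta, int depth_, int base_) {
    depth = depth_; base = base_;
    spec = layer_specs(depth, base);
    W.clear(); b.clear();
    long off = 0;
    for (const auto& s : spec) {
      long nw = (long)s.cout * s.cin * s.k * s.k;
      W.push_back(reshape(theta.subvec(off, off + nw - 1), s.cout, s.cin * s.k * s.k));
      off += nw;
      b.push_back(theta.subvec(off, off + s.cout - 1));
      off += s.cout;
    }
  }

  vec to_flat() const {
    vec th(n_params(spec));
    long off = 0;
    for (size_t i = 0; i < W.size(); ++i) {
      th.subvec(off, off + W[i].n_elem - 1) = vectorise(W[i]);
      off += W[i].n_elem;
      th.subvec(off, off + b[i].n_elem - 1) = b[i];
      off += b[i].n_elem;
    }
    return th;
  }
};

// im2col for 3x3, zero pad 1. X: cin x (H*W) -> cin*9 x (H*W).
// Row block order: offset (dr, dc) with dr fastest, dr,dc in {-1,0,1}.
void im2col3(const mat& X, int H, int Wd, mat& out) {
  int cin = X.n_rows;
  out.set_size(cin * 9, (size_t)H * Wd);
  out.zeros();
  int blk = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++blk) {
      // out(blk rows, pixel (r,c)) = X(:, (r+dr, c+dc)) when inside
      int c0 = std::max(0, -dc), c1 = std::min(Wd, Wd - dc);
      int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      if (c0 >= c1 || r0 >= r1) continue;
      for (int c = c0; c < c1; ++c) {
        size_t dst = (size_t)c * H + r0;
        size_t src = (size_t)(c + dc) * H + (r0 + dr);
        out.submat(blk * cin, dst, (blk + 1) * cin - 1, dst + (r1 - r0) - 1) =
            X.cols(src, src + (r1 - r0) - 1);
      }
    }
  }
}

// col2im: accumulate cin*9 x (H*W) gradient back to cin x (H*W).
void col2im3(const mat& G, int H, int Wd, mat& out) {
  int cin = G.n_rows / 9;
  out.set_size(cin, (size_t)H * Wd);
  out.zeros();
  int blk = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++blk) {
      int c0 = std::max(0, -dc), c1 = std::min(Wd, Wd - dc);
      int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      if (c0 >= c1 || r0 >= r1) continue;
      for (int c = c0; c < c1; ++c) {
        size_t dst = (size_t)(c + dc) * H + (r0 + dr);
        size_t src = (size_t)c * H + r0;
        out.cols(dst, dst + (r1 - r0) - 1) +=
            G.submat(blk * cin, src, (blk + 1) * cin - 1, src + (r1 - r0) - 1);
      }
    }
  }
}

mat conv_fwd(const Net& net, int li, const mat& X, int H, int Wd, mat& col_cache) {
  const ConvSpec& s = net.spec[li];
  mat Y;
  if (s.k == 1) {
    col_cache = X;
    Y = net.W[li] * X;
  } else {
    im2col3(X, H, Wd, col_cache);
    Y = net.W[li] * col_cache;
  }
  Y.each_col() += net.b[li];
  return Y;
}

// dY -> dX; accumulates dW, db.
mat conv_bwd(const Net& net, int li, const mat& dY, const mat& col_cache,
             int H, int Wd, mat& dW, vec& db) {
  const ConvSpec& s = net.spec[li];
  dW += dY * col_cache.t();
  db += sum(dY, 1);
  mat dcol = net.W[li].t() * dY;
  if (s.k == 1) return dcol;
  mat dX;
  col2im3(dcol, H, Wd, dX);
  return dX;
}

// 2x2 max pool; records argmax pixel index for backward.
mat maxpool(const mat& X, int H, int Wd, umat& arg, int& Ho, int& Wo) {
  Ho = H / 2; Wo = Wd / 2;
  int C = X.n_rows;
  mat Y(C, (size_t)Ho * Wo);
  arg.set_size(C, (size_t)Ho * Wo);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      size_t p = (size_t)c * Ho + r;
      size_t q[4] = {(size_t)(2 * c) * H + 2 * r, (size_t)(2 * c) * H + 2 * r + 1,
                     (size_t)(2 * c + 1) * H + 2 * r, (size_t)(2 * c + 1) * H + 2 * r + 1};
      for (int ch = 0; ch < C; ++ch) {
        double best = X(ch, q[0]); size_t bi = q[0];
        for (int t = 1; t < 4; ++t)
          if (X(ch, q[t]) > best) { best = X(ch, q[t]); bi = q[t]; }
        Y(ch, p) = best; arg(ch, p) = bi;
      }
    }
  }
  return Y;
}

mat maxpool_bwd(const mat& dY, const umat& arg, int H, int Wd) {
  mat dX(dY.n_rows, (size_t)H * Wd, fill::zeros);
  for (size_t p = 0; p < dY.n_cols; ++p)
    for (size_t ch = 0; ch < dY.n_rows; ++ch)
      dX(ch, arg(ch, p)) += dY(ch, p);
  return dX;
}

// Nearest-neighbour 2x upsample.
mat upsample(const mat& X, int H, int Wd) {
  int Ho = H * 2, Wo = Wd * 2;
  mat Y(X.n_rows, (size_t)Ho * Wo);
  for (int c = 0; c < Wo; ++c)
    for (int r = 0; r < Ho; ++r)
      Y.col((size_t)c * Ho + r) = X.col((size_t)(c / 2) * H + r / 2);
  return Y;
}

mat upsample_bwd(const mat& dY, int H, int Wd) {
  // H, Wd are the *input* (coarse) dims
  mat dX(dY.n_rows, (size_t)H * Wd, fill::zeros);
  int Ho = H * 2;
  for (int c = 0; c < 2 * Wd; ++c)
    for (int r = 0; r < Ho; ++r)
      dX.col((size_t)(c / 2) * H + r / 2) += dY.col((size_t)c * Ho + r);
  return dX;
}

mat relu_mask(const mat& a) { return conv_to<mat>::from(a > 0); }

struct FwdCache {
  std::vector<mat> cols;     // per conv layer im2col cache
  std::vector<mat> acts;     // per conv layer post-ReLU activation (for ReLU mask)
  std::vector<umat> poolarg;
  std::vector<mat> skips;    // encoder outputs per level
  std::vector<std::pair<int,int>> dims; // per conv layer (H, W)
  mat prob;                  // sigmoid output 1 x H*W
};

// Full forward pass; X0: 1 x (H*W).
void forward(const Net& net, const mat& X0, int H, int Wd, FwdCache& fc) {
  int D = net.depth;
  size_t nl = net.spec.size();
  fc.cols.assign(nl, mat());
  fc.acts.assign(nl, mat());
  fc.dims.assign(nl, {0, 0});
  fc.poolarg.assign(D - 1, umat());
  fc.skips.assign(D, mat());
  mat X = X0;
  int h = H, w = Wd;
  int li = 0;
  for (int l = 0; l < D; ++l) {
    if (l > 0) {
      int ho, wo;
      X = maxpool(X, h, w, fc.poolarg[l - 1], ho, wo);
      h = ho; w = wo;
    }
    for (int t = 0; t < 2; ++t, ++li) {
      X = conv_fwd(net, li, X, h, w, fc.cols[li]);
      X.transform([](float v) { return v > 0 ? v : 0.0f; }); // ReLU
      fc.acts[li] = X;
      fc.dims[li] = {h, w};
    }
    fc.skips[l] = X;
  }
  for (int l = D - 2; l >= 0; --l) {
    X = upsample(X, h, w);
    h *= 2; w *= 2;
    X = conv_fwd(net, li, X, h, w, fc.cols[li]);
    X.transform([](float v) { return v > 0 ? v : 0.0f; });
    fc.acts[li] = X; fc.dims[li] = {h, w};
    ++li;
    X = join_cols(fc.skips[l], X); // concat skip on top
    for (int t = 0; t < 2; ++t, ++li) {
      X = conv_fwd(net, li, X, h, w, fc.cols[li]);
      X.transform([](float v) { return v > 0 ? v : 0.0f; });
      fc.acts[li] = X; fc.dims[li] = {h, w};
    }
  }
  // output 1x1 conv + sigmoid (no ReLU); logits clamped to +-30 so saturated
  // probabilities bottom out at ~1e-13 instead of denormals (denormal-laden
  // GEMMs are catastrophically slow on common CPUs)
  mat Z = conv_fwd(net, li, X, h, w, fc.cols[li]);
  Z.clamp(-30.0f, 30.0f);
  fc.dims[li] = {h, w};
  fc.prob = 1.0f / (1.0f + exp(-Z));
}

// Soft Tversky index on one sample. p, t: 1 x N.
double tversky(const mat& p, const mat& t, double alpha, double beta,
               double eps, double* denom_out = nullptr, double* inter_out = nullptr) {
  double inter = accu(conv_to<arma::mat>::from(p % t));
  double fn = accu(conv_to<arma::mat>::from((1.0f - p) % t));
  double fp = accu(conv_to<arma::mat>::from(p % (1.0f - t)));
  double denom = inter + alpha * fn + beta * fp + eps;
  if (denom_out) *denom_out = denom;
  if (inter_out) *inter_out = inter;
  return inter / denom;
}

// Backward pass from Tversky loss (loss = 1 - index); accumulates grads.
void backward(const Net& net, const FwdCache& fc, const mat& X0, const mat& target,
              double alpha, double beta, double eps,
              std::vector<mat>& dW, std::vector<vec>& db) {
  int D = net.depth;
  int li = (int)net.spec.size() - 1;
  const mat& p = fc.prob;
  double denom, inter;
  tversky(p, target, alpha, beta, eps, &denom, &inter);
  // d(1-T)/dp = -(t*denom - inter * dDenom/dp) / denom^2,
  // dDenom/dp = t - alpha*t + beta*(1-t)
  mat dT = (target * (float)denom -
            (float)inter * (target - (float)alpha * target +
                            (float)beta * (1.0f - target))) /
           (float)(denom * denom);
  mat dZ = (-dT) % p % (1.0f - p); // through sigmoid
  int h = fc.dims[li].first, w = fc.dims[li].second;
  mat dX = conv_bwd(net, li, dZ, fc.cols[li], h, w, dW[li], db[li]);
  --li;
  for (int l = 0; l < D - 1; ++l) {
    for (int t = 0; t < 2; ++t, --li) {
      dX %= relu_mask(fc.acts[li]);
      h = fc.dims[li].first; w = fc.dims[li].second;
      dX = conv_bwd(net, li, dX, fc.cols[li], h, w, dW[li], db[li]);
    }
    // split concat: top rows were skip, bottom rows the up-conv output
    int cskip = fc.skips[l].n_rows;
    mat dSkip = dX.rows(0, cskip - 1);
    mat dUp = dX.rows(cskip, dX.n_rows - 1);
    dUp %= relu_mask(fc.acts[li]);
    h = fc.dims[li].first; w = fc.dims[li].second;
    dUp = conv_bwd(net, li, dUp, fc.cols[li], h, w, dW[li], db[li]);
    --li;
    dX = upsample_bwd(dUp, h / 2, w / 2);
    // skip-connection gradient is folded in when the encoder walk reaches
    // this level; reuse the cache slot to carry it
    const_cast<FwdCache&>(fc).skips[l] = dSkip;
  }
  // encoder backward, from bottleneck (level D-1) down to level 0
  for (int l = D - 1; l >= 0; --l) {
    if (l < D - 1) {
      // dX currently at pooled resolution of level l; un-pool
      int hp = fc.dims[li].first, wp = fc.dims[li].second;
      dX = maxpool_bwd(dX, fc.poolarg[l], hp, wp);
      dX += const_cast<FwdCache&>(fc).skips[l]; // add skip-connection gradient
    }
    for (int t = 0; t < 2; ++t, --li) {
      dX %= relu_mask(fc.acts[li]);
      h = fc.dims[li].first; w = fc.dims[li].second;
      dX = conv_bwd(net, li, dX, fc.cols[li], h, w, dW[li], db[li]);
    }
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector unet_init_cpp(int depth, int base_channels, int seed) {
  auto sp = layer_specs(depth, base_channels);
  arma::vec th(n_params(sp), fill::zeros);
  std::mt19937 gen((unsigned)seed);
  long off = 0;
  for (const auto& s : sp) {
    long nw = (long)s.cout * s.cin * s.k * s.k;
    double sd = std::sqrt(2.0 / (s.cin * s.k * s.k)); // He init
    std::normal_distribution<double> nd(0.0, sd);
    for (long i = 0; i < nw; ++i) th(off + i) = nd(gen);
    off += nw + s.cout; // biases stay zero
  }
  return Rcpp::wrap(th);
}

// patches: H*W x n matrices (each column one patch, column-major pixels)
// [[Rcpp::export]]
Rcpp::List unet_train_cpp(const arma::mat& train_x_d, const arma::mat& train_y_d,
                          const arma::mat& val_x_d, const arma::mat& val_y_d,
                          Rcpp::NumericVector weights, int patch_h, int patch_w,
                          int depth, int base_channels,
                          double alpha, double beta, double lr,
                          int epochs, int batch_size, int seed, double eps) {
  fmat train_x = conv_to<arma::fmat>::from(train_x_d);
  fmat train_y = conv_to<arma::fmat>::from(train_y_d);
  fmat val_x = conv_to<arma::fmat>::from(val_x_d);
  fmat val_y = conv_to<arma::fmat>::from(val_y_d);
  set_ftz();
  Net net;
  net.from_flat(conv_to<arma::fvec>::from(Rcpp::as<arma::vec>(weights)), depth,
                base_channels);
  size_t nl = net.spec.size();
  std::vector<fmat> mW(nl), vW(nl);
  std::vector<fvec> mb(nl), vb(nl);
  for (size_t i = 0; i < nl; ++i) {
    mW[i].zeros(size(net.W[i])); vW[i].zeros(size(net.W[i]));
    mb[i].zeros(net.b[i].n_elem); vb[i].zeros(net.b[i].n_elem);
  }
  int n = train_x.n_cols;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  arma::vec train_log(epochs, fill::zeros), val_log(epochs, fill::zeros);
  double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  long step = 0;
  bool diverged = false;
  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    std::mt19937 gen((unsigned)(seed + 1000L * ep));
    std::shuffle(idx.begin(), idx.end(), gen);
    double ep_loss = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bend = std::min(n, start + batch_size);
      std::vector<fmat> dW(nl);
      std::vector<fvec> db(nl);
      for (size_t i = 0; i < nl; ++i) {
        dW[i].zeros(size(net.W[i])); db[i].zeros(net.b[i].n_elem);
      }
      double bloss = 0;
      for (int bi = start; bi < bend; ++bi) {
        fmat x = train_x.col(idx[bi]).t(); // 1 x H*W
        fmat y = train_y.col(idx[bi]).t();
        FwdCache fc;
        forward(net, x, patch_h, patch_w, fc);
        double tv = tversky(fc.prob, y, alpha, beta, eps);
        bloss += 1.0 - tv;
        backward(net, fc, x, y, alpha, beta, eps, dW, db);
      }
      int bs = bend - start;
      ep_loss += bloss;
      if (!std::isfinite(bloss)) { diverged = true; break; }
      ++step;
      double corr = std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < nl; ++i) {
        dW[i] /= bs; db[i] /= bs;
        mW[i] = (float)b1 * mW[i] + (float)(1 - b1) * dW[i];
        vW[i] = (float)b2 * vW[i] + (float)(1 - b2) * square(dW[i]);
        net.W[i] -= (float)(lr * corr) * mW[i] / (sqrt(vW[i]) + (float)adam_eps);
        mb[i] = (float)b1 * mb[i] + (float)(1 - b1) * db[i];
        vb[i] = (float)b2 * vb[i] + (float)(1 - b2) * square(db[i]);
        net.b[i] -= (float)(lr * corr) * mb[i] / (sqrt(vb[i]) + (float)adam_eps);
      }
    }
    train_log(ep) = ep_loss / n;
    double vloss = 0;
    for (size_t j = 0; j < val_x.n_cols; ++j) {
      fmat x = val_x.col(j).t(), y = val_y.col(j).t();
      FwdCache fc;
      forward(net, x, patch_h, patch_w, fc);
      vloss += 1.0 - tversky(fc.prob, y, alpha, beta, eps);
    }
    val_log(ep) = vloss / std::max((uword)1, val_x.n_cols);
    if (diverged) { train_log(ep) = arma::datum::nan; }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::wrap(conv_to<arma::vec>::from(net.to_flat())),
      Rcpp::Named("train_loss") = Rcpp::wrap(train_log),
      Rcpp::Named("val_loss") = Rcpp::wrap(val_log),
      Rcpp::Named("diverged") = diverged);
}

// img: H x W matrix; returns probability map H x W. H, W must be divisible
// by 2^(depth-1) (the R wrapper pads).
// [[Rcpp::export]]
arma::mat unet_predict_cpp(Rcpp::NumericVector weights, const arma::mat& img,
                           int depth, int base_channels) {
  set_ftz();
  Net net;
  net.from_flat(conv_to<arma::fvec>::from(Rcpp::as<arma::vec>(weights)), depth,
                base_channels);
  int H = img.n_rows, Wd = img.n_cols;
  fmat x = reshape(conv_to<arma::fmat>::from(img), 1, (size_t)H * Wd);
  FwdCache fc;
  forward(net, x, H, Wd, fc);
  return conv_to<arma::mat>::from(reshape(fc.prob, H, Wd));
}

// Numerical-check helper: loss on one patch (for gradient tests from R).
// [[Rcpp::export]]
double unet_loss_cpp(Rcpp::NumericVector weights, const arma::mat& img,
                     const arma::mat& target, int depth, int base_channels,
                     double alpha, double beta, double eps) {
  set_ftz();
  Net net;
  net.from_flat(conv_to<arma::fvec>::from(Rcpp::as<arma::vec>(weights)), depth,
                base_channels);
  int H = img.n_rows, Wd = img.n_cols;
  fmat x = reshape(conv_to<arma::fmat>::from(img), 1, (size_t)H * Wd);
  fmat y = reshape(conv_to<arma::fmat>::from(target), 1, (size_t)H * Wd);
  FwdCache fc;
  forward(net, x, H, Wd, fc);
  return 1.0 - tversky(fc.prob, y, alpha, beta, eps);
}

// Analytic gradient of the loss on one patch (flat), for finite-difference checks.
// [[Rcpp::export]]
Rcpp::NumericVector unet_grad_cpp(Rcpp::NumericVector weights, const arma::mat& img,
                                  const arma::mat& target, int depth, int base_channels,
                                  double alpha, double beta, double eps) {
  set_ftz();
  Net net;
  net.from_flat(conv_to<arma::fvec>::from(Rcpp::as<arma::vec>(weights)), depth,
                base_channels);
  int H = img.n_rows, Wd = img.n_cols;
  fmat x = reshape(conv_to<arma::fmat>::from(img), 1, (size_t)H * Wd);
  fmat y = reshape(conv_to<arma::fmat>::from(target), 1, (size_t)H * Wd);
  FwdCache fc;
  forward(net, x, H, Wd, fc);
  size_t nl = net.spec.size();
  std::vector<fmat> dW(nl);
  std::vector<fvec> db(nl);
  for (size_t i = 0; i < nl; ++i) {
    dW[i].zeros(size(net.W[i])); db[i].zeros(net.b[i].n_elem);
  }
  backward(net, fc, x, y, alpha, beta, eps, dW, db);
  Net g; g.spec = net.spec; g.depth = depth; g.base = base_channels;
  g.W = dW; g.b = db;
  return Rcpp::wrap(conv_to<arma::vec>::from(g.to_flat()));
}
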