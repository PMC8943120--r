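// Multi-label patch-quality network: a small residual CNN family
// (3x3 conv + batch-norm basic blocks, global average pooling, linear
// 6-output head) trained by Adam on Huber loss. Implemented directly on
// Armadillo GEMM via im2col; feature maps are stored channels x
// (N * H * W) with the spatial index fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;

// ---------- im2col / col2im (pad 1 for 3x3, pad 0 for 1x1) ----------

static void im2col3(const mat& A, int C, int H, int W, int N, int stride,
                    mat& K, int& Ho, int& Wo) {
  Ho = (H + 2 - 3) / stride + 1;
  Wo = (W + 2 - 3) / stride + 1;
  K.zeros(C * 9, (size_t)N * Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const size_t in_off = (size_t)n * H * W;
    const size_t out_off = (size_t)n * Ho * Wo;
    for (int yo = 0; yo < Ho; ++yo) {
      for (int xo = 0; xo < Wo; ++xo) {
        const size_t col = out_off + (size_t)yo * Wo + xo;
        double* kptr = K.colptr(col);
        for (int ky = 0; ky < 3; ++ky) {
          const int y = yo * stride + ky - 1;
          if (y < 0 || y >= H) continue;
          for (int kx = 0; kx < 3; ++kx) {
            const int x = xo * stride + kx - 1;
            if (x < 0 || x >= W) continue;
            const double* aptr = A.colptr(in_off + (size_t)y * W + x);
            const int krow = ky * 3 + kx;
            for (int c = 0; c < C; ++c) kptr[c * 9 + krow] = aptr[c];
          }
        }
      }
    }
  }
}

static void col2im3(const mat& dK, int C, int H, int W, int N, int stride,
                    int Ho, int Wo, mat& dA) {
  dA.zeros(C, (size_t)N * H * W);
  for (int n = 0; n < N; ++n) {
    const size_t in_off = (size_t)n * H * W;
    const size_t out_off = (size_t)n * Ho * Wo;
    for (int yo = 0; yo < Ho; ++yo) {
      for (int xo = 0; xo < Wo; ++xo) {
        const size_t col = out_off + (size_t)yo * Wo + xo;
        const double* kptr = dK.colptr(col);
        for (int ky = 0; ky < 3; ++ky) {
          const int y = yo * stride + ky - 1;
          if (y < 0 || y >= H) continue;
          for (int kx = 0; kx < 3; ++kx) {
            const int x = xo * stride + kx - 1;
            if (x < 0 || x >= W) continue;
            double* aptr = dA.colptr(in_off + (size_t)y * W + x);
            const int krow = ky * 3 + kx;
            for (int c = 0; c < C; ++c) aptr[c] += kptr[c * 9 + krow];
          }
        }
      }
    }
  }
}

// 1x1 conv "im2col": subsample columns by stride.
static uvec subsample_cols(int H, int W, int N, int stride, int& Ho, int& Wo) {
  Ho = (H - 1) / stride + 1;
  Wo = (W - 1) / stride + 1;
  uvec idx((size_t)N * Ho * Wo);
  size_t k = 0;
  for (int n = 0; n < N; ++n)
    for (int y = 0; y < H; y += stride)
      for (int x = 0; x < W; x += stride)
        idx(k++) = (size_t)n * H * W + (size_t)y * W + x;
  return idx;
}

// ---------- optimiser ----------

template <typename T>
struct Adam {
  T m, v;
  bool init = false;
  void step(T& w, const T& g, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    if (!init) { m.zeros(size(w)); v.zeros(size(w)); init = true; }
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }
};

// ---------- layers ----------

struct ConvBN {
  int cin = 0, cout = 0, stride = 1, ksize = 3;
  mat W;                    // cout x (cin * k * k)
  vec gamma, beta, rmean, rvar;
  // caches
  mat K; uvec sub_idx; mat xhat; vec invstd;
  int H = 0, Wd = 0, N = 0, Ho = 0, Wo = 0;
  // grads + adam state
  mat dW; vec dgamma, dbeta;
  Adam<mat> aW; Adam<vec> ag, ab;

  mat forward(const mat& A, int H_, int W_, int N_, bool train, double mom) {
    H = H_; Wd = W_; N = N_;
    mat Y;
    if (ksize == 3) {
      im2col3(A, cin, H, Wd, N, stride, K, Ho, Wo);
      Y = W * K;
    } else {
      sub_idx = subsample_cols(H, Wd, N, stride, Ho, Wo);
      K = A.cols(sub_idx);
      Y = W * K;
    }
    if (train) {
      vec mu = mean(Y, 1);
      Y.each_col() -= mu;
      vec va = mean(square(Y), 1);
      invstd = 1.0 / sqrt(va + BN_EPS);
      Y.each_col() %= invstd;
      xhat = Y;
      rmean = (1 - mom) * rmean + mom * mu;
      rvar = (1 - mom) * rvar + mom * va;
      Y.each_col() %= gamma;
      Y.each_col() += beta;
    } else {
      vec is = 1.0 / sqrt(rvar + BN_EPS);
      Y.each_col() -= rmean;
      Y.each_col() %= (gamma % is);
      Y.each_col() += beta;
    }
    return Y;
  }

  // dY -> gradient wrt layer input (also fills parameter grads)
  mat backward(const mat& dY) {
    dgamma = sum(dY % xhat, 1);
    dbeta = sum(dY, 1);
    mat dx = dY;
    dx.each_col() %= gamma;
    vec mdx = mean(dx, 1);
    vec mdxx = mean(dx % xhat, 1);
    dx.each_col() -= mdx;
    dx -= xhat.each_col() % mdxx;
    dx.each_col() %= invstd;
    dW = dx * K.t();
    mat dK = W.t() * dx;
    mat dA;
    if (ksize == 3) {
      col2im3(dK, cin, H, Wd, N, stride, Ho, Wo, dA);
    } else {
      dA.zeros(cin, (size_t)N * H * Wd);
      dA.cols(sub_idx) = dK;
    }
    return dA;
  }

  void update(double lr, int t) {
    aW.step(W, dW, lr, t);
    ag.step(gamma, dgamma, lr, t);
    ab.step(beta, dbeta, lr, t);
  }
};

// Standalone batch norm (used on the pooled embedding before the linear
// head, so the head sees standardised, signed features).
struct BN1d {
  vec gamma, beta, rmean, rvar;
  mat xhat; vec invstd;
  vec dgamma, dbeta;
  Adam<vec> ag, ab;

  mat forward(const mat& X, bool train, double mom) {
    mat Y = X;
    if (train) {
      vec mu = mean(Y, 1);
      Y.each_col() -= mu;
      vec va = mean(square(Y), 1);
      invstd = 1.0 / sqrt(va + BN_EPS);
      Y.each_col() %= invstd;
      xhat = Y;
      rmean = (1 - mom) * rmean + mom * mu;
      rvar = (1 - mom) * rvar + mom * va;
    } else {
      vec is = 1.0 / sqrt(rvar + BN_EPS);
      Y.each_col() -= rmean;
      Y.each_col() %= is;
      xhat = Y;
    }
    Y.each_col() %= gamma;
    Y.each_col() += beta;
    return Y;
  }

  mat backward(const mat& dY) {
    dgamma = sum(dY % xhat, 1);
    dbeta = sum(dY, 1);
    mat dx = dY;
    dx.each_col() %= gamma;
    vec mdx = mean(dx, 1);
    vec mdxx = mean(dx % xhat, 1);
    dx.each_col() -= mdx;
    dx -= xhat.each_col() % mdxx;
    dx.each_col() %= invstd;
    return dx;
  }

  void update(double lr, int t) {
    ag.step(gamma, dgamma, lr, t);
    ab.step(beta, dbeta, lr, t);
  }
};

static inline mat relu_mask(mat& h) {
  mat mask = conv_to<mat>::from(h > 0);
  h %= mask;
  return mask;
}

struct Block {
  ConvBN conv1, conv2;
  bool has_proj = false;
  ConvBN proj;
  mat mask1, mask_out;

  mat forward(const mat& A, int H, int W, int N, bool train, double mom,
              int& Ho, int& Wo) {
    mat h = conv1.forward(A, H, W, N, train, mom);
    mask1 = relu_mask(h);
    mat y = conv2.forward(h, conv1.Ho, conv1.Wo, N, train, mom);
    if (has_proj) y += proj.forward(A, H, W, N, train, mom);
    else y += A;
    mask_out = relu_mask(y);
    Ho = conv2.Ho; Wo = conv2.Wo;
    return y;
  }

  mat backward(const mat& dY) {
    mat d = dY % mask_out;
    mat dh = conv2.backward(d);
    dh %= mask1;
    mat dA = conv1.backward(dh);
    if (has_proj) dA += proj.backward(d);
    else dA += d;
    return dA;
  }

  void update(double lr, int t) {
    conv1.update(lr, t);
    conv2.update(lr, t);
    if (has_proj) proj.update(lr, t);
  }
};

struct Net {
  ConvBN stem;
  std::vector<Block> blocks;
  BN1d bn_head;
  mat fcW; vec fcb;
  mat dfcW; vec dfcb;
  Adam<mat> afw; Adam<vec> afb;
  int in_size = 64;
  // caches
  mat stem_mask, pooled, z_head;
  int pH = 0, pW = 0, pN = 0;

  mat forward(const mat& X, int N, bool train, double mom) {
    int H = in_size, W = in_size;
    // columns of X are flattened patches (3 channel blocks of H*W);
    // rearrange to channels x (N*H*W) with the spatial index fastest
    const int HW = H * W;
    mat a0(3, (size_t)N * HW);
    for (int n = 0; n < N; ++n) {
      const double* src = X.colptr(n);
      for (int c = 0; c < 3; ++c) {
        double* dst = &a0.at(c, (size_t)n * HW);
        const double* s = src + (size_t)c * HW;
        for (int p = 0; p < HW; ++p) dst[(size_t)p * 3] = s[p];
      }
    }
    mat a = stem.forward(a0, H, W, N, train, mom);
    stem_mask = relu_mask(a);
    H = stem.Ho; W = stem.Wo;
    for (auto& b : blocks) {
      int Ho, Wo;
      a = b.forward(a, H, W, N, train, mom, Ho, Wo);
      H = Ho; W = Wo;
    }
    pH = H; pW = W; pN = N;
    pooled.set_size(a.n_rows, N);
    for (int n = 0; n < N; ++n)
      pooled.col(n) = mean(a.cols((size_t)n * H * W, (size_t)(n + 1) * H * W - 1), 1);
    z_head = bn_head.forward(pooled, train, mom);
    mat out = fcW * z_head;
    out.each_col() += fcb;
    return out;
  }

  void backward(const mat& dOut) {
    dfcW = dOut * z_head.t();
    dfcb = sum(dOut, 1);
    mat dpool = bn_head.backward(fcW.t() * dOut);   // channels x N
    const double hw = (double)pH * pW;
    mat da(dpool.n_rows, (size_t)pN * pH * pW);
    for (int n = 0; n < pN; ++n) {
      vec g = dpool.col(n) / hw;
      da.cols((size_t)n * pH * pW, (size_t)(n + 1) * pH * pW - 1).each_col() = g;
    }
    for (int i = (int)blocks.size() - 1; i >= 0; --i)
      da = blocks[i].backward(da);
    da %= stem_mask;
    stem.backward(da);
  }

  void update(double lr, int t) {
    stem.update(lr, t);
    for (auto& b : blocks) b.update(lr, t);
    bn_head.update(lr, t);
    afw.step(fcW, dfcW, lr, t);
    afb.step(fcb, dfcb, lr, t);
  }
};

// ---------- parameter packing ----------

static void load_convbn(ConvBN& c, const Rcpp::List& par, int& i) {
  c.W = Rcpp::as<mat>(par[i++]);
  c.gamma = Rcpp::as<vec>(par[i++]);
  c.beta = Rcpp::as<vec>(par[i++]);
  c.rmean = Rcpp::as<vec>(par[i++]);
  c.rvar = Rcpp::as<vec>(par[i++]);
  c.cout = c.W.n_rows;
}

static Net build_net(const std::vector<int>& widths,
                     const std::vector<int>& nblocks, int in_size,
                     const Rcpp::List& par) {
  Net net;
  net.in_size = in_size;
  int i = 0;
  net.stem.cin = 3; net.stem.stride = 2; net.stem.ksize = 3;
  load_convbn(net.stem, par, i);
  int cin = widths[0];
  for (size_t s = 0; s < widths.size(); ++s) {
    for (int b = 0; b < nblocks[s]; ++b) {
      Block blk;
      int stride = (s > 0 && b == 0) ? 2 : 1;
      blk.conv1.cin = cin; blk.conv1.stride = stride; blk.conv1.ksize = 3;
      load_convbn(blk.conv1, par, i);
      blk.conv2.cin = widths[s]; blk.conv2.stride = 1; blk.conv2.ksize = 3;
      load_convbn(blk.conv2, par, i);
      if (stride != 1 || cin != widths[s]) {
        blk.has_proj = true;
        blk.proj.cin = cin; blk.proj.stride = stride; blk.proj.ksize = 1;
        load_convbn(blk.proj, par, i);
      }
      cin = widths[s];
      net.blocks.push_back(std::move(blk));
    }
  }
  net.bn_head.gamma = Rcpp::as<vec>(par[i++]);
  net.bn_head.beta = Rcpp::as<vec>(par[i++]);
  net.bn_head.rmean = Rcpp::as<vec>(par[i++]);
  net.bn_head.rvar = Rcpp::as<vec>(par[i++]);
  net.fcW = Rcpp::as<mat>(par[i++]);
  net.fcb = Rcpp::as<vec>(par[i++]);
  if (i != par.size()) Rcpp::stop("parameter list does not match architecture");
  return net;
}

static void store_convbn(const ConvBN& c, Rcpp::List& par, int& i) {
  par[i++] = c.W;
  par[i++] = Rcpp::wrap(c.gamma); par[i++] = Rcpp::wrap(c.beta);
  par[i++] = Rcpp::wrap(c.rmean); par[i++] = Rcpp::wrap(c.rvar);
}

static Rcpp::List dump_params(const Net& net, int n_par) {
  Rcpp::List par(n_par);
  int i = 0;
  store_convbn(net.stem, par, i);
  for (const auto& b : net.blocks) {
    store_convbn(b.conv1, par, i);
    store_convbn(b.conv2, par, i);
    if (b.has_proj) store_convbn(b.proj, par, i);
  }
  par[i++] = Rcpp::wrap(net.bn_head.gamma);
  par[i++] = Rcpp::wrap(net.bn_head.beta);
  par[i++] = Rcpp::wrap(net.bn_head.rmean);
  par[i++] = Rcpp::wrap(net.bn_head.rvar);
  par[i++] = net.fcW;
  par[i++] = Rcpp::wrap(net.fcb);
  return par;
}

// ---------- loss ----------

static double huber(const mat& diff, double delta) {
  mat a = abs(diff);
  mat l = 0.5 * square(diff);
  uvec big = find(a > delta);
  vec ab = a.elem(big);
  l.elem(big) = delta * ab - 0.5 * delta * delta;
  return accu(l) / (double)l.n_elem;
}

static mat huber_grad(const mat& diff, double delta) {
  return clamp(diff, -delta, delta) / (double)diff.n_elem;
}

// ---------- exported entry points ----------

// [[Rcpp::export(name = ".qnet_train_cpp")]]
Rcpp::List qnet_train_cpp(const arma::mat& X, const arma::mat& Y,
                          const arma::mat& Xval, const arma::mat& Yval,
                          std::vector<int> widths, std::vector<int> nblocks,
                          int in_size, Rcpp::List params,
                          Rcpp::IntegerMatrix order, int batch_size,
                          double lr, double delta, double bn_momentum) {
  Net net = build_net(widths, nblocks, in_size, params);
  const int n_par = params.size();
  const int epochs = order.nrow();
  const size_t nval = Xval.n_cols;

  auto eval_loss = [&](void) -> double {
    if (nval == 0) return NA_REAL;
    double tot = 0; size_t seen = 0;
    for (size_t s = 0; s < nval; s += batch_size) {
      size_t e = std::min(nval, s + (size_t)batch_size);
      mat out = net.forward(Xval.cols(s, e - 1), (int)(e - s), false, bn_momentum);
      tot += huber(out - Yval.cols(s, e - 1), delta) * (double)(e - s);
      seen += e - s;
    }
    return tot / (double)seen;
  };

  std::vector<double> train_hist(epochs, NA_REAL), val_hist(epochs + 1, NA_REAL);
  val_hist[0] = eval_loss();
  double best_val = val_hist[0];
  Rcpp::List best = dump_params(net, n_par);
  int best_epoch = 0, t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0; int nb = 0;
    const int n_ep = order.ncol();
    for (int s = 0; s < n_ep; s += batch_size) {
      int e = std::min(n_ep, s + batch_size);
      if (e - s < 2) break;  // batch norm needs > 1 sample
      uvec idx(e - s);
      for (int k = s; k < e; ++k) idx(k - s) = (uword)(order(ep, k) - 1);
      mat xb = X.cols(idx), yb = Y.cols(idx);
      mat out = net.forward(xb, e - s, true, bn_momentum);
      mat diff = out - yb;
      double l = huber(diff, delta);
      if (!std::isfinite(l))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
      ep_loss += l; ++nb;
      net.backward(huber_grad(diff, delta));
      net.update(lr, ++t);
    }
    train_hist[ep] = ep_loss / std::max(nb, 1);
    val_hist[ep + 1] = eval_loss();
    if (nval > 0 && val_hist[ep + 1] < best_val) {
      best_val = val_hist[ep + 1];
      best = dump_params(net, n_par);
      best_epoch = ep + 1;
    }
    Rcpp::checkUserInterrupt();
  }
  if (nval == 0) { best = dump_params(net, n_par); best_epoch = epochs; }
  return Rcpp::List::create(
    Rcpp::Named("params") = best,
    Rcpp::Named("final_params") = dump_params(net, n_par),
    Rcpp::Named("train_loss") = train_hist,
    Rcpp::Named("val_loss") = val_hist,
    Rcpp::Named("best_epoch") = best_epoch);
}

// Loss and parameter gradients for one batch (training mode); used to
// check the backward pass against finite differences.
// [[Rcpp::export(name = ".qnet_lossgrad_cpp")]]
Rcpp::List qnet_lossgrad_cpp(const arma::mat& X, const arma::mat& Y,
                             std::vector<int> widths, std::vector<int> nblocks,
                             int in_size, Rcpp::List params, double delta) {
  Net net = build_net(widths, nblocks, in_size, params);
  mat out = net.forward(X, X.n_cols, true, 0.0);
  mat diff = out - Y;
  double l = huber(diff, delta);
  net.backward(huber_grad(diff, delta));
  // gradients in canonical parameter order (running stats -> zero)
  Rcpp::List grads(params.size());
  int i = 0;
  auto store_g = [&](const ConvBN& c) {
    grads[i++] = c.dW;
    grads[i++] = Rcpp::wrap(c.dgamma); grads[i++] = Rcpp::wrap(c.dbeta);
    grads[i++] = Rcpp::wrap(vec(c.rmean.n_elem, fill::zeros));
    grads[i++] = Rcpp::wrap(vec(c.rvar.n_elem, fill::zeros));
  };
  store_g(net.stem);
  for (const auto& b : net.blocks) {
    store_g(b.conv1);
    store_g(b.conv2);
    if (b.has_proj) store_g(b.proj);
  }
  grads[i++] = Rcpp::wrap(net.bn_head.dgamma);
  grads[i++] = Rcpp::wrap(net.bn_head.dbeta);
  grads[i++] = Rcpp::wrap(vec(net.bn_head.rmean.n_elem, fill::zeros));
  grads[i++] = Rcpp::wrap(vec(net.bn_head.rvar.n_elem, fill::zeros));
  grads[i++] = net.dfcW;
  grads[i++] = Rcpp::wrap(net.dfcb);
  return Rcpp::List::create(Rcpp::Named("loss") = l,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export(name = ".qnet_forward_cpp")]]
arma::mat qnet_forward_cpp(const arma::mat& X, std::vector<int> widths,
                           std::vector<int> nblocks, int in_size,
                           Rcpp::List params, int batch_size,
                           bool features = false) {
  Net net = build_net(widths, nblocks, in_size, params);
  const size_t n = X.n_cols;
  mat out;
  for (size_t s = 0; s < n; s += batch_size) {
    size_t e = std::min(n, s + (size_t)batch_size);
    mat o = net.forward(X.cols(s, e - 1), (int)(e - s), false, 0.1);
    if (features) o = net.pooled;
    if (out.n_elem == 0) out.set_size(o.n_rows, n);
    out.cols(s, e - 1) = o;
  }
  return out;
}

// [[Rcpp::export(name = ".clamp01_cpp")]]
Rcpp::NumericVector clamp01_cpp(Rcpp::NumericVector x) {
  Rcpp::NumericVector y = Rcpp::clone(x);
  for (double& v : y) { if (v < 0) v = 0; else if (v > 1) v = 1; }
  return y;
}
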