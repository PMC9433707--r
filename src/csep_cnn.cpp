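// Compiled core of the convolutional intelligibility classifier.
//
// The network is small and fixed in shape (four same-padding convolutions,
// leaky ReLU, three 2x2 max-pools with strides 2/1/1, one batch-norm, one
// fully-connected softmax head), so the implementation is a direct
// im2col + GEMM forward/backward pass with an Adam optimizer, in single
// precision. Activations are stored per image as (H*W) x C matrices with
// column-major pixel index p = w*H + h, which makes a convolution one
// matrix product per image.
//
// Determinism: all randomness (weight init, shuffling, validation split)
// comes from a std::mt19937 seeded from R, and execution is single-threaded,
// so identical inputs + seed give bit-identical results.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

enum LayerType { CONV = 0, LRELU = 1, POOL = 2, BN = 3, DENSE = 4, SOFTMAX = 5 };

struct Shape {
  int H = 0, W = 0, C = 0;
  int size() const { return H * W * C; }
};

struct Layer {
  int type = 0;
  // conv / dense parameters (+ Adam state)
  int k = 0, Cout = 0, pb = 0;
  fmat W, dW, mW, vW;
  fvec b, db, mb, vb;
  // pooling
  int psize = 2, pstride = 2;
  std::vector<umat> argm;
  // batch norm
  fvec gamma, beta, rmean, rvar, dgamma, dbeta, mg, vg, mbeta, vbeta, istd;
  std::vector<fmat> xhat;
  // leaky relu
  float slope = 0.01f;
  // caches
  std::vector<fmat> in;   // input activations (conv, pool, lrelu)
  fmat dense_in;          // D x B
  Shape in_shape, out_shape;
};

// ---- im2col / col2im -------------------------------------------------------

// Patch matrix in (H*W) x (k*k*C) layout: one column per kernel offset, so
// the inner copies run contiguously down the pixel dimension.
static fmat im2col(const fmat& X, int H, int W, int k, int pb) {
  const int C = X.n_cols;
  fmat out((size_t)H * W, (size_t)k * k * C, arma::fill::none);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      const int dw = kj - pb;
      for (int ki = 0; ki < k; ++ki) {
        const int dh = ki - pb;
        const size_t col = (size_t)ki + (size_t)k * kj + (size_t)k * k * c;
        float* oc = out.colptr(col);
        const int wlo = std::max(0, -dw), whi = std::min(W, W - dw);
        const int hlo = std::max(0, -dh), hhi = std::min(H, H - dh);
        if (wlo > 0) std::memset(oc, 0, sizeof(float) * (size_t)wlo * H);
        if (whi < W) std::memset(oc + (size_t)whi * H, 0,
                                 sizeof(float) * (size_t)(W - whi) * H);
        for (int wo = wlo; wo < whi; ++wo) {
          float* dst = oc + (size_t)wo * H;
          if (hlo > 0) std::memset(dst, 0, sizeof(float) * hlo);
          if (hhi < H) std::memset(dst + hhi, 0, sizeof(float) * (H - hhi));
          std::memcpy(dst + hlo, xc + (size_t)(wo + dw) * H + dh + hlo,
                      sizeof(float) * (hhi - hlo));
        }
      }
    }
  }
  return out;
}

static void col2im_acc(const fmat& cols, fmat& dX, int H, int W, int k, int pb) {
  const int C = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    float* xc = dX.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      const int dw = kj - pb;
      for (int ki = 0; ki < k; ++ki) {
        const int dh = ki - pb;
        const size_t col = (size_t)ki + (size_t)k * kj + (size_t)k * k * c;
        const float* sc = cols.colptr(col);
        const int wlo = std::max(0, -dw), whi = std::min(W, W - dw);
        const int hlo = std::max(0, -dh), hhi = std::min(H, H - dh);
        for (int wo = wlo; wo < whi; ++wo) {
          float* dst = xc + (size_t)(wo + dw) * H + dh + hlo;
          const float* src = sc + (size_t)wo * H + hlo;
          for (int ho = 0; ho < hhi - hlo; ++ho)
            dst[ho] += src[ho];
        }
      }
    }
  }
}

// ---- spec parsing ----------------------------------------------------------

static std::vector<Layer> parse_spec(const List& spec, const Shape& input,
                                     std::vector<Shape>& bounds) {
  std::vector<Layer> layers(spec.size());
  Shape cur = input;
  bounds.clear();
  bounds.push_back(cur);
  for (int i = 0; i < spec.size(); ++i) {
    List ls = spec[i];
    std::string ty = as<std::string>(ls["type"]);
    Layer& L = layers[i];
    L.in_shape = cur;
    if (ty == "conv") {
      L.type = CONV;
      L.k = as<int>(ls["kernel"]);
      L.Cout = as<int>(ls["filters"]);
      L.pb = (L.k - 1) / 2;           // same padding (asymmetric for even k)
      cur.C = L.Cout;                  // H, W preserved
    } else if (ty == "leaky_relu") {
      L.type = LRELU;
      L.slope = ls.containsElementNamed("slope") ? as<float>(ls["slope"]) : 0.01f;
    } else if (ty == "maxpool") {
      L.type = POOL;
      L.psize = as<int>(ls["size"]);
      L.pstride = as<int>(ls["stride"]);
      cur.H = (cur.H - L.psize) / L.pstride + 1;
      cur.W = (cur.W - L.psize) / L.pstride + 1;
    } else if (ty == "batchnorm") {
      L.type = BN;
    } else if (ty == "dense") {
      L.type = DENSE;
      L.Cout = as<int>(ls["units"]);
      cur = Shape{1, 1, L.Cout};
    } else if (ty == "softmax") {
      L.type = SOFTMAX;
    } else {
      stop("unknown layer type: " + ty);
    }
    L.out_shape = cur;
    bounds.push_back(cur);
  }
  return layers;
}

static void load_weights(std::vector<Layer>& layers, const List& weights) {
  for (size_t i = 0; i < layers.size(); ++i) {
    Layer& L = layers[i];
    if (L.type == CONV || L.type == DENSE) {
      List wl = weights[i];
      L.W = as<fmat>(wl["W"]);
      L.b = as<fvec>(wl["b"]);
      L.dW.zeros(L.W.n_rows, L.W.n_cols);
      L.db.zeros(L.b.n_elem);
      L.mW.zeros(L.W.n_rows, L.W.n_cols); L.vW.zeros(L.W.n_rows, L.W.n_cols);
      L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
    } else if (L.type == BN) {
      List wl = weights[i];
      L.gamma = as<fvec>(wl["gamma"]);
      L.beta = as<fvec>(wl["beta"]);
      L.rmean = as<fvec>(wl["running_mean"]);
      L.rvar = as<fvec>(wl["running_var"]);
      int C = L.gamma.n_elem;
      L.dgamma.zeros(C); L.dbeta.zeros(C);
      L.mg.zeros(C); L.vg.zeros(C); L.mbeta.zeros(C); L.vbeta.zeros(C);
    }
  }
}

static List dump_weights(const std::vector<Layer>& layers) {
  List out(layers.size());
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& L = layers[i];
    if (L.type == CONV || L.type == DENSE) {
      out[i] = List::create(_["W"] = wrap(L.W), _["b"] = wrap(L.b));
    } else if (L.type == BN) {
      out[i] = List::create(_["gamma"] = wrap(L.gamma), _["beta"] = wrap(L.beta),
                            _["running_mean"] = wrap(L.rmean),
                            _["running_var"] = wrap(L.rvar));
    } else {
      out[i] = R_NilValue;
    }
  }
  return out;
}

// ---- forward / backward ----------------------------------------------------

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// batch: per-image activations (HW x C). Returns logits-softmax probs K x B.
static fmat forward_batch(std::vector<Layer>& layers, std::vector<fmat>& batch,
                          bool training, bool keep_cache) {
  const int B = batch.size();
  fmat probs;
  for (size_t li = 0; li < layers.size(); ++li) {
    Layer& L = layers[li];
    const Shape in = L.in_shape, out = L.out_shape;
    switch (L.type) {
    case CONV: {
      if (keep_cache) L.in = batch;
      for (int i = 0; i < B; ++i) {
        fmat cols = im2col(batch[i], in.H, in.W, L.k, L.pb);
        fmat O = cols * L.W.t();                 // HW x Cout
        O.each_row() += L.b.t();
        batch[i] = std::move(O);
      }
      break;
    }
    case LRELU: {
      if (keep_cache) L.in = batch;
      for (int i = 0; i < B; ++i) {
        fmat& A = batch[i];
        A.transform([&](float v) { return v > 0 ? v : L.slope * v; });
      }
      break;
    }
    case POOL: {
      if (keep_cache) { L.in = batch; L.argm.assign(B, umat()); }
      for (int i = 0; i < B; ++i) {
        const fmat& A = batch[i];
        fmat O((size_t)out.H * out.W, in.C);
        umat AM;
        if (keep_cache) AM.set_size((size_t)out.H * out.W, in.C);
        for (int c = 0; c < in.C; ++c) {
          const float* ac = A.colptr(c);
          for (int wo = 0; wo < out.W; ++wo) {
            for (int ho = 0; ho < out.H; ++ho) {
              const int h0 = ho * L.pstride, w0 = wo * L.pstride;
              float best = -std::numeric_limits<float>::infinity();
              size_t bidx = 0;
              for (int dw = 0; dw < L.psize; ++dw) {
                for (int dh = 0; dh < L.psize; ++dh) {
                  const size_t idx = (size_t)(w0 + dw) * in.H + (h0 + dh);
                  const float v = ac[idx];
                  if (v > best) { best = v; bidx = idx; }
                }
              }
              O((size_t)wo * out.H + ho, c) = best;
              if (keep_cache) AM((size_t)wo * out.H + ho, c) = bidx;
            }
          }
        }
        batch[i] = O;
        if (keep_cache) L.argm[i] = AM;
      }
      break;
    }
    case BN: {
      const int C = in.C;
      const double m = (double)B * in.H * in.W;
      fvec mu(C), var(C);
      if (training) {
        for (int c = 0; c < C; ++c) {
          double s = 0, s2 = 0;
          for (int i = 0; i < B; ++i) {
            const fvec col = batch[i].col(c);
            s += arma::accu(col);
            s2 += arma::dot(col, col);
          }
          mu[c] = (float)(s / m);
          var[c] = (float)(s2 / m - (s / m) * (s / m));
          if (var[c] < 0) var[c] = 0;
        }
        L.rmean = (1.0f - BN_MOMENTUM) * L.rmean + BN_MOMENTUM * mu;
        L.rvar = (1.0f - BN_MOMENTUM) * L.rvar + BN_MOMENTUM * var;
      } else {
        mu = L.rmean;
        var = L.rvar;
      }
      L.istd = 1.0f / arma::sqrt(var + BN_EPS);
      if (keep_cache) L.xhat.assign(B, fmat());
      for (int i = 0; i < B; ++i) {
        fmat& A = batch[i];
        fmat xh = A;
        for (int c = 0; c < C; ++c)
          xh.col(c) = (A.col(c) - mu[c]) * L.istd[c];
        if (keep_cache) L.xhat[i] = xh;
        for (int c = 0; c < C; ++c)
          A.col(c) = L.gamma[c] * xh.col(c) + L.beta[c];
      }
      break;
    }
    case DENSE: {
      const int D = in.size();
      fmat Xf(D, B);
      for (int i = 0; i < B; ++i)
        Xf.col(i) = arma::vectorise(batch[i]);
      if (keep_cache) L.dense_in = Xf;
      fmat logits = L.W * Xf;                    // K x B
      logits.each_col() += L.b;
      for (int i = 0; i < B; ++i)
        batch[i] = logits.col(i);                // K x 1
      break;
    }
    case SOFTMAX: {
      const int K = out.C;
      probs.set_size(K, B);
      for (int i = 0; i < B; ++i) {
        fvec z = batch[i].col(0);
        z -= z.max();
        fvec e = arma::exp(z);
        probs.col(i) = e / arma::accu(e);
      }
      break;
    }
    }
  }
  return probs;
}

// dlogits: K x B gradient at the softmax input.
static void backward_batch(std::vector<Layer>& layers, const fmat& dlogits) {
  const int B = dlogits.n_cols;
  std::vector<fmat> grad;   // per-image gradient wrt current layer input
  fmat gdense = dlogits;
  for (int li = (int)layers.size() - 1; li >= 0; --li) {
    Layer& L = layers[li];
    const Shape in = L.in_shape;
    switch (L.type) {
    case SOFTMAX:
      break;                                  // folded into dlogits
    case DENSE: {
      L.dW = gdense * L.dense_in.t();
      L.db = arma::sum(gdense, 1);
      fmat dX = L.W.t() * gdense;             // D x B
      grad.assign(B, fmat());
      for (int i = 0; i < B; ++i)
        grad[i] = fmat(dX.colptr(i), (size_t)in.H * in.W, in.C);
      break;
    }
    case BN: {
      const int C = in.C;
      const double m = (double)B * in.H * in.W;
      L.dgamma.zeros(C); L.dbeta.zeros(C);
      for (int i = 0; i < B; ++i)
        for (int c = 0; c < C; ++c) {
          L.dgamma[c] += arma::dot(grad[i].col(c), L.xhat[i].col(c));
          L.dbeta[c] += arma::accu(grad[i].col(c));
        }
      for (int i = 0; i < B; ++i) {
        fmat& G = grad[i];
        for (int c = 0; c < C; ++c) {
          G.col(c) = (L.gamma[c] * L.istd[c]) *
            (G.col(c) - (float)(L.dbeta[c] / m) -
             L.xhat[i].col(c) * (float)(L.dgamma[c] / m));
        }
      }
      break;
    }
    case POOL: {
      const Shape out = L.out_shape;
      for (int i = 0; i < B; ++i) {
        fmat dX((size_t)in.H * in.W, in.C, arma::fill::zeros);
        const fmat& G = grad[i];
        const umat& AM = L.argm[i];
        for (int c = 0; c < in.C; ++c) {
          float* dxc = dX.colptr(c);
          const float* gc = G.colptr(c);
          const arma::uword* am = AM.colptr(c);
          const size_t np = (size_t)out.H * out.W;
          for (size_t p = 0; p < np; ++p)
            dxc[am[p]] += gc[p];
        }
        grad[i] = dX;
      }
      L.argm.clear(); L.in.clear();
      break;
    }
    case LRELU: {
      for (int i = 0; i < B; ++i) {
        const fmat& X = L.in[i];
        fmat& G = grad[i];
        const size_t n = X.n_elem;
        const float* xp = X.memptr();
        float* gp = G.memptr();
        for (size_t j = 0; j < n; ++j)
          if (xp[j] <= 0) gp[j] *= L.slope;
      }
      L.in.clear();
      break;
    }
    case CONV: {
      L.dW.zeros(); L.db.zeros();
      std::vector<fmat> dXs(B);
      for (int i = 0; i < B; ++i) {
        fmat cols = im2col(L.in[i], in.H, in.W, L.k, L.pb);
        const fmat& gout = grad[i];            // HW x Cout
        L.dW += gout.t() * cols;               // Cout x kkC
        L.db += arma::sum(gout, 0).t();
        fmat dcols = gout * L.W;               // HW x kkC
        fmat dX((size_t)in.H * in.W, in.C, arma::fill::zeros);
        col2im_acc(dcols, dX, in.H, in.W, L.k, L.pb);
        dXs[i] = dX;
      }
      grad = dXs;
      L.in.clear();
      break;
    }
    }
  }
}

static void adam_update(fmat& P, const fmat& G, fmat& M, fmat& V,
                        double lr, double b1, double b2, double eps, int t) {
  M = (float)b1 * M + (float)(1 - b1) * G;
  V = (float)b2 * V + (float)(1 - b2) * (G % G);
  const double mc = 1 - std::pow(b1, t), vc = 1 - std::pow(b2, t);
  P -= (float)(lr / mc) * (M / (arma::sqrt(V / (float)vc) + (float)eps));
}

static void adam_update_vec(fvec& P, const fvec& G, fvec& M, fvec& V,
                            double lr, double b1, double b2, double eps, int t) {
  M = (float)b1 * M + (float)(1 - b1) * G;
  V = (float)b2 * V + (float)(1 - b2) * (G % G);
  const double mc = 1 - std::pow(b1, t), vc = 1 - std::pow(b2, t);
  P -= (float)(lr / mc) * (M / (arma::sqrt(V / (float)vc) + (float)eps));
}

// ---- image marshalling -----------------------------------------------------

// x: H x W x C x N (R array, double). Returns per-image (HW x C) floats.
static std::vector<fmat> unpack_images(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("image array must be H x W x C x N");
  const size_t H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t per = H * W * C;
  std::vector<fmat> out(N);
  const double* xp = x.begin();
  for (size_t i = 0; i < N; ++i) {
    fmat A(H * W, C);
    float* ap = A.memptr();
    const double* src = xp + i * per;
    for (size_t j = 0; j < per; ++j) ap[j] = (float)src[j];
    out[i] = std::move(A);
  }
  return out;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
List cnn_init_cpp(List spec, IntegerVector input_dim, int seed) {
  Shape in{input_dim[0], input_dim[1], input_dim[2]};
  std::vector<Shape> bounds;
  std::vector<Layer> layers = parse_spec(spec, in, bounds);
  std::mt19937 rng((unsigned)seed);
  List out(layers.size());
  for (size_t i = 0; i < layers.size(); ++i) {
    Layer& L = layers[i];
    if (L.type == CONV) {
      const int fin = L.k * L.k * L.in_shape.C;
      const int fout = L.k * L.k * L.Cout;
      const float lim = std::sqrt(6.0f / (fin + fout));
      std::uniform_real_distribution<float> U(-lim, lim);
      fmat W(L.Cout, fin);
      for (size_t j = 0; j < W.n_elem; ++j) W[j] = U(rng);
      out[i] = List::create(_["W"] = wrap(W),
                            _["b"] = wrap(fvec(L.Cout, arma::fill::zeros)));
    } else if (L.type == DENSE) {
      const int D = L.in_shape.size();
      const float lim = std::sqrt(6.0f / (D + L.Cout));
      std::uniform_real_distribution<float> U(-lim, lim);
      fmat W(L.Cout, D);
      for (size_t j = 0; j < W.n_elem; ++j) W[j] = U(rng);
      out[i] = List::create(_["W"] = wrap(W),
                            _["b"] = wrap(fvec(L.Cout, arma::fill::zeros)));
    } else if (L.type == BN) {
      const int C = L.in_shape.C;
      out[i] = List::create(_["gamma"] = wrap(fvec(C, arma::fill::ones)),
                            _["beta"] = wrap(fvec(C, arma::fill::zeros)),
                            _["running_mean"] = wrap(fvec(C, arma::fill::zeros)),
                            _["running_var"] = wrap(fvec(C, arma::fill::ones)));
    } else {
      out[i] = R_NilValue;
    }
  }
  return out;
}

// Actual forward shape trace: runs one zero image through the network and
// records the concrete (H, W, C) of every layer's output tensor.
// [[Rcpp::export]]
IntegerMatrix cnn_trace_cpp(List spec, List weights, IntegerVector input_dim) {
  Shape in{input_dim[0], input_dim[1], input_dim[2]};
  std::vector<Shape> bounds;
  std::vector<Layer> layers = parse_spec(spec, in, bounds);
  load_weights(layers, weights);
  std::vector<fmat> batch{fmat((size_t)in.H * in.W, in.C, arma::fill::zeros)};
  IntegerMatrix out(layers.size(), 3);
  for (size_t li = 0; li < layers.size(); ++li) {
    std::vector<Layer> one{layers[li]};
    forward_batch(one, batch, false, false);
    if (one[0].type == SOFTMAX) {
      // forward_batch returns probs separately; batch already holds logits
      out(li, 0) = 1; out(li, 1) = 1; out(li, 2) = batch[0].n_elem;
      continue;
    }
    const Shape& s = layers[li].out_shape;
    // record the *observed* tensor dims (HW x C matrix) split by the
    // declared H; consistency between the two is checked here.
    if ((int)batch[0].n_elem != s.size())
      stop("layer %d produced %d values, expected %d",
           (int)li + 1, (int)batch[0].n_elem, s.size());
    out(li, 0) = s.H; out(li, 1) = s.W; out(li, 2) = s.C;
  }
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector x, IntegerVector y, List spec, List weights,
                   List cfg) {
  std::vector<fmat> images = unpack_images(x);
  const int N = images.size();
  if ((int)y.size() != N) stop("length(y) != number of images");
  IntegerVector d = x.attr("dim");
  Shape in{d[0], d[1], d[2]};
  std::vector<Shape> bounds;
  std::vector<Layer> layers = parse_spec(spec, in, bounds);
  load_weights(layers, weights);
  const int K = layers.back().out_shape.C;

  const double lr = as<double>(cfg["learning_rate"]);
  const int batch_size = as<int>(cfg["batch_size"]);
  const int epochs = as<int>(cfg["epochs"]);
  const double val_frac = as<double>(cfg["validation_fraction"]);
  const bool shuffle = as<bool>(cfg["shuffle"]);
  const unsigned seed = (unsigned)as<int>(cfg["seed"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::mt19937 rng(seed);
  std::vector<int> idx(N);
  std::iota(idx.begin(), idx.end(), 0);
  std::shuffle(idx.begin(), idx.end(), rng);
  const int n_val = (int)std::lround(val_frac * N);
  std::vector<int> val_idx(idx.begin(), idx.begin() + n_val);
  std::vector<int> tr_idx(idx.begin() + n_val, idx.end());

  auto eval_on = [&](const std::vector<int>& which, double& loss, double& acc) {
    double ls = 0; int ok = 0;
    const int chunk = std::max(1, batch_size);
    for (size_t s = 0; s < which.size(); s += chunk) {
      const size_t e = std::min(which.size(), s + chunk);
      std::vector<fmat> b;
      for (size_t j = s; j < e; ++j) b.push_back(images[which[j]]);
      fmat probs = forward_batch(layers, b, false, false);
      for (size_t j = s; j < e; ++j) {
        const int yi = y[which[j]];
        const float p = probs(yi, j - s);
        ls += -std::log(std::max(p, 1e-12f));
        if ((int)probs.col(j - s).index_max() == yi) ++ok;
      }
    }
    loss = which.empty() ? NA_REAL : ls / which.size();
    acc = which.empty() ? NA_REAL : (double)ok / which.size();
  };

  NumericMatrix history(epochs, 5);
  colnames(history) = CharacterVector::create(
    "epoch", "train_loss", "train_acc", "val_loss", "val_acc");
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) std::shuffle(tr_idx.begin(), tr_idx.end(), rng);
    double ep_loss = 0; int ep_ok = 0;
    for (size_t s = 0; s < tr_idx.size(); s += batch_size) {
      const size_t e = std::min(tr_idx.size(), s + batch_size);
      const int B = e - s;
      std::vector<fmat> batch;
      batch.reserve(B);
      for (size_t j = s; j < e; ++j) batch.push_back(images[tr_idx[j]]);
      fmat probs = forward_batch(layers, batch, true, true);
      fmat dlogits = probs;
      for (int i = 0; i < B; ++i) {
        const int yi = y[tr_idx[s + i]];
        ep_loss += -std::log(std::max(probs(yi, i), 1e-12f));
        if ((int)probs.col(i).index_max() == yi) ++ep_ok;
        dlogits(yi, i) -= 1.0f;
      }
      dlogits /= (float)B;
      backward_batch(layers, dlogits);
      ++t;
      for (Layer& L : layers) {
        if (L.type == CONV || L.type == DENSE) {
          adam_update(L.W, L.dW, L.mW, L.vW, lr, b1, b2, eps, t);
          adam_update_vec(L.b, L.db, L.mb, L.vb, lr, b1, b2, eps, t);
        } else if (L.type == BN) {
          adam_update_vec(L.gamma, L.dgamma, L.mg, L.vg, lr, b1, b2, eps, t);
          adam_update_vec(L.beta, L.dbeta, L.mbeta, L.vbeta, lr, b1, b2, eps, t);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    double vl, va;
    eval_on(val_idx, vl, va);
    history(ep, 0) = ep + 1;
    history(ep, 1) = tr_idx.empty() ? NA_REAL : ep_loss / tr_idx.size();
    history(ep, 2) = tr_idx.empty() ? NA_REAL : (double)ep_ok / tr_idx.size();
    history(ep, 3) = vl;
    history(ep, 4) = va;
  }
  return List::create(_["weights"] = dump_weights(layers),
                      _["history"] = history,
                      _["n_val"] = n_val);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericVector x, List spec, List weights,
                              int batch_size) {
  std::vector<fmat> images = unpack_images(x);
  const int N = images.size();
  IntegerVector d = x.attr("dim");
  Shape in{d[0], d[1], d[2]};
  std::vector<Shape> bounds;
  std::vector<Layer> layers = parse_spec(spec, in, bounds);
  load_weights(layers, weights);
  const int K = layers.back().out_shape.C;
  NumericMatrix out(N, K);
  for (int s = 0; s < N; s += batch_size) {
    const int e = std::min(N, s + batch_size);
    std::vector<fmat> b(images.begin() + s, images.begin() + e);
    fmat probs = forward_batch(layers, b, false, false);
    for (int i = s; i < e; ++i)
      for (int k = 0; k < K; ++k)
        out(i, k) = probs(k, i - s);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
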