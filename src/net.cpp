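// Compute kernels for the length-stratified 1D-CNN phage lifestyle
// classifier: Markov-chain genome sampling, batched forward pass, and a
// full forward/backward/Adam training loop.
//
// All randomness (dropout masks, epoch shuffles, chain sampling) is drawn
// from R's RNG via R::unif_rand(), so set.seed() on the R side makes every
// exported routine deterministic under the single-threaded contract.
//
// Base codes throughout: 0=T, 1=G, 2=C, 3=A (matching the one-hot column
// order), 4 = ambiguous or padding (contributes an all-zero one-hot row).
// The exception is cpp_markov_chain, whose states are the caller's
// transition-matrix row/column order (A,C,G,T on the R side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Markov-chain genome sampler
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_markov_chain(NumericMatrix transition, int len, int order) {
  if (len < 1) stop("len must be >= 1");
  if (order < 1) stop("order must be >= 1");
  IntegerVector out(len);
  for (int i = 0; i < order && i < len; ++i) {
    int b = (int)(R::unif_rand() * 4.0);
    out[i] = b > 3 ? 3 : b;
  }
  for (int i = order; i < len; ++i) {
    int ctx = 0;
    for (int j = i - order; j < i; ++j) ctx = ctx * 4 + out[j];
    double u = R::unif_rand(), acc = 0.0;
    int b = 3;
    for (int k = 0; k < 4; ++k) {
      acc += transition(ctx, k);
      if (u < acc) { b = k; break; }
    }
    out[i] = b;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Network plumbing
// ---------------------------------------------------------------------------

struct NetConf {
  int L, F, M, S1, S2, R;
  int Lp;     // pooled length (number of complete windows)
  int Din;    // dense-1 input dimension
  int K;      // k-mer feature dimension (kmer front end only)
  double P, eps, momentum;
  bool conv, pool, bn, dropout, gpool;
};

static NetConf conf_from_list(List cf) {
  NetConf c;
  c.L  = as<int>(cf["L"]);   c.F  = as<int>(cf["F"]);
  c.M  = as<int>(cf["M"]);   c.S1 = as<int>(cf["S1"]);
  c.S2 = as<int>(cf["S2"]);  c.R  = as<int>(cf["R"]);
  c.K  = as<int>(cf["K"]);
  c.P = as<double>(cf["P"]);
  c.eps = as<double>(cf["bn_epsilon"]);
  c.momentum = as<double>(cf["bn_momentum"]);
  c.conv    = as<bool>(cf["use_conv"]);
  c.pool    = as<bool>(cf["use_pool"]);
  c.bn      = as<bool>(cf["use_bn"]);
  c.dropout = as<bool>(cf["use_dropout"]);
  c.gpool   = as<bool>(cf["use_gpool"]);
  if (c.conv) {
    c.Lp = c.pool ? ((c.L - c.S1) / c.S2 + 1) : c.L;
    c.Din = c.gpool ? c.F : c.F * c.Lp;
  } else {
    c.Lp = 0;
    c.Din = c.K;
  }
  return c;
}

struct NetParams {
  arma::mat wc;                    // F x (M*4)
  arma::vec bc;                    // F
  arma::vec g1, be1, rm1, rv1;     // F (BN1)
  arma::mat w1;                    // R x Din
  arma::vec b1;                    // R
  arma::vec g2, be2, rm2, rv2;     // R (BN2)
  arma::vec w2;                    // R
  double b2;
};

static NetParams params_from_list(List w) {
  NetParams p;
  p.wc  = as<arma::mat>(w["conv_Wf"]);
  p.bc  = as<arma::vec>(w["conv_b"]);
  p.g1  = as<arma::vec>(w["bn1_scale"]);
  p.be1 = as<arma::vec>(w["bn1_shift"]);
  p.rm1 = as<arma::vec>(w["bn1_mean"]);
  p.rv1 = as<arma::vec>(w["bn1_var"]);
  p.w1  = as<arma::mat>(w["dense1_W"]);
  p.b1  = as<arma::vec>(w["dense1_b"]);
  p.g2  = as<arma::vec>(w["bn2_scale"]);
  p.be2 = as<arma::vec>(w["bn2_shift"]);
  p.rm2 = as<arma::vec>(w["bn2_mean"]);
  p.rv2 = as<arma::vec>(w["bn2_var"]);
  p.w2  = as<arma::vec>(w["dense2_W"]);
  p.b2  = as<double>(w["dense2_b"]);
  return p;
}

static List params_to_list(const NetParams& p) {
  return List::create(
    _["conv_Wf"] = p.wc, _["conv_b"] = p.bc,
    _["bn1_scale"] = p.g1, _["bn1_shift"] = p.be1,
    _["bn1_mean"] = p.rm1, _["bn1_var"] = p.rv1,
    _["dense1_W"] = p.w1, _["dense1_b"] = p.b1,
    _["bn2_scale"] = p.g2, _["bn2_shift"] = p.be2,
    _["bn2_mean"] = p.rm2, _["bn2_var"] = p.rv2,
    _["dense2_W"] = p.w2, _["dense2_b"] = p.b2);
}

static inline void relu_inplace(arma::mat& x) {
  x.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// Conv1D with zero right-padding so output length stays L; bias and ReLU
// fused. Yc is F x (L*B): column b*L + l holds feature map values at
// position l. Raw-pointer loops: this is the hot path.
static void conv_forward(const IntegerMatrix& X, const arma::uvec& idx,
                         const NetConf& cf, const NetParams& p, arma::mat& Yc) {
  const int B = idx.n_elem, F = cf.F, L = cf.L, M = cf.M;
  Yc.zeros(F, (arma::uword)L * B);
  const double* bc = p.bc.memptr();
  for (int b = 0; b < B; ++b) {
    const int* Xcol = &X(0, idx[b]);
    double* Y0 = Yc.colptr((arma::uword)b * L);
    for (int m = 0; m < M; ++m) {
      const double* Wm = p.wc.colptr(m * 4);
      for (int pos = m; pos < L; ++pos) {
        const int c = Xcol[pos];
        if (c < 4) {
          double* dst = Y0 + (arma::uword)(pos - m) * F;
          const double* w = Wm + (arma::uword)c * F;
          for (int f = 0; f < F; ++f) dst[f] += w[f];
        }
      }
    }
    // fused bias + ReLU
    for (int l = 0; l < L; ++l) {
      double* col = Y0 + (arma::uword)l * F;
      for (int f = 0; f < F; ++f) {
        const double v = col[f] + bc[f];
        col[f] = v > 0.0 ? v : 0.0;
      }
    }
  }
}

static void maxpool_forward(const arma::mat& Yc, int B, const NetConf& cf,
                            arma::mat& Ym, arma::umat& amax) {
  const int F = cf.F;
  Ym.set_size(F, (arma::uword)cf.Lp * B);
  amax.set_size(F, (arma::uword)cf.Lp * B);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < cf.Lp; ++w) {
      const double* src = Yc.colptr((arma::uword)b * cf.L +
                                    (arma::uword)w * cf.S2);
      double* m = Ym.colptr((arma::uword)b * cf.Lp + w);
      arma::uword* a = amax.colptr((arma::uword)b * cf.Lp + w);
      for (int f = 0; f < F; ++f) { m[f] = src[f]; a[f] = 0; }
      for (int s = 1; s < cf.S1; ++s) {
        const double* c = src + (arma::uword)s * F;
        for (int f = 0; f < F; ++f)
          if (c[f] > m[f]) { m[f] = c[f]; a[f] = s; }
      }
    }
  }
}

// Batch normalization, training mode: normalizes with batch statistics,
// updates running moments in place, returns caches for the backward pass.
static void bn_forward_train(arma::mat& x, const arma::vec& g, const arma::vec& be,
                             arma::vec& rm, arma::vec& rv, double eps, double mom,
                             arma::mat& xhat, arma::vec& istd) {
  const double N = (double)x.n_cols;
  arma::vec mu = arma::mean(x, 1);
  x.each_col() -= mu;
  arma::vec var = arma::sum(arma::square(x), 1) / N;  // biased
  istd = 1.0 / arma::sqrt(var + eps);
  x.each_col() %= istd;
  xhat = x;
  x.each_col() %= g;
  x.each_col() += be;
  rm = mom * rm + (1.0 - mom) * mu;
  rv = mom * rv + (1.0 - mom) * var;
}

static void bn_forward_infer(arma::mat& x, const arma::vec& g, const arma::vec& be,
                             const arma::vec& rm, const arma::vec& rv, double eps) {
  arma::vec istd = 1.0 / arma::sqrt(rv + eps);
  x.each_col() -= rm;
  x.each_col() %= (g % istd);
  x.each_col() += be;
}

static arma::mat bn_backward(const arma::mat& dout, const arma::mat& xhat,
                             const arma::vec& istd, const arma::vec& g,
                             arma::vec& dg, arma::vec& dbe) {
  const double N = (double)dout.n_cols;
  dg = arma::sum(dout % xhat, 1);
  dbe = arma::sum(dout, 1);
  arma::mat t = dout.each_col() % (g % istd);
  arma::vec s1 = arma::sum(t, 1);
  arma::vec s2 = arma::sum(t % xhat, 1);
  t.each_col() -= s1 / N;
  t -= xhat.each_col() % (s2 / N);
  return t;
}

static inline double sigmoid1(double z) {
  return z >= 0.0 ? 1.0 / (1.0 + std::exp(-z))
                  : std::exp(z) / (1.0 + std::exp(z));
}

// Caches kept from a training-mode forward pass for backpropagation.
struct FwdCache {
  arma::mat Yc;        // post-ReLU conv maps, F x L*B
  arma::mat Ym;        // pooled (or alias of Yc when pooling disabled)
  arma::umat amax;
  arma::mat xhat1; arma::vec istd1;
  arma::mat mask;      // dropout mask (already includes 1/(1-P))
  arma::mat Z;         // dense-1 input, Din x B
  arma::mat H1;        // post-ReLU dense-1, R x B
  arma::mat xhat2; arma::vec istd2;
  arma::mat H2;        // dense-2 input, R x B
  arma::rowvec s;      // sigmoid scores
};

// Full forward pass for one batch. `X` holds integer base codes with one
// column per sequence (L x n). `Xfeat` (K x n) is used instead when the
// k-mer front end is active.
static arma::rowvec net_forward(const IntegerMatrix& X, const arma::mat& Xfeat,
                                const arma::uvec& idx, const NetConf& cf,
                                NetParams& p, bool train, FwdCache* cc) {
  const int B = idx.n_elem;
  arma::mat Z;  // dense-1 input
  FwdCache local;
  FwdCache& c = cc ? *cc : local;
  if (cf.conv) {
    conv_forward(X, idx, cf, p, c.Yc);
    if (cf.pool) maxpool_forward(c.Yc, B, cf, c.Ym, c.amax);
    else c.Ym = c.Yc;
    if (cf.bn) {
      if (train) bn_forward_train(c.Ym, p.g1, p.be1, p.rm1, p.rv1, cf.eps,
                                  cf.momentum, c.xhat1, c.istd1);
      else bn_forward_infer(c.Ym, p.g1, p.be1, p.rm1, p.rv1, cf.eps);
    }
    if (cf.dropout && train) {
      const double keep = 1.0 - cf.P, scale = 1.0 / keep;
      c.mask.set_size(c.Ym.n_rows, c.Ym.n_cols);
      for (arma::uword j = 0; j < c.mask.n_elem; ++j)
        c.mask[j] = (R::unif_rand() < cf.P) ? 0.0 : scale;
      c.Ym %= c.mask;
    }
    const int Lp = cf.pool ? cf.Lp : cf.L;
    if (cf.gpool) {
      Z.set_size(cf.F, B);
      for (int b = 0; b < B; ++b)
        Z.col(b) = arma::mean(c.Ym.cols((arma::uword)b * Lp,
                                        (arma::uword)(b + 1) * Lp - 1), 1);
    } else {
      // flatten each sequence's F x Lp block column-major
      Z = arma::reshape(c.Ym, (arma::uword)cf.F * Lp, B);
    }
  } else {
    Z.set_size(cf.K, B);
    for (int b = 0; b < B; ++b) Z.col(b) = Xfeat.col(idx[b]);
  }
  c.Z = Z;
  arma::mat H1 = p.w1 * Z;
  H1.each_col() += p.b1;
  relu_inplace(H1);
  c.H1 = H1;
  if (cf.bn) {
    if (train) bn_forward_train(H1, p.g2, p.be2, p.rm2, p.rv2, cf.eps,
                                cf.momentum, c.xhat2, c.istd2);
    else bn_forward_infer(H1, p.g2, p.be2, p.rm2, p.rv2, cf.eps);
  }
  c.H2 = H1;
  arma::rowvec z = p.w2.t() * H1;
  z += p.b2;
  arma::rowvec s(B);
  for (int b = 0; b < B; ++b) s[b] = sigmoid1(z[b]);
  c.s = s;
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_forward_batch(IntegerMatrix X, NumericMatrix Xfeat,
                                List weights, List conf) {
  NetConf cf = conf_from_list(conf);
  NetParams p = params_from_list(weights);
  arma::mat feat = as<arma::mat>(Xfeat);
  const int n = cf.conv ? X.ncol() : feat.n_cols;
  NumericVector out(n);
  const int chunk = 64;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int s1 = std::min(n, s0 + chunk);
    arma::uvec idx(s1 - s0);
    for (int i = s0; i < s1; ++i) idx[i - s0] = i;
    arma::rowvec sc = net_forward(X, feat, idx, cf, p, false, nullptr);
    for (int i = s0; i < s1; ++i) out[i] = sc[i - s0];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Training
// ---------------------------------------------------------------------------

struct AdamState {
  std::vector<arma::mat> m, v;
  long t = 0;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
};

static void adam_step(AdamState& st, std::vector<arma::mat*>& params,
                      std::vector<arma::mat>& grads) {
  st.t += 1;
  const double c1 = 1.0 - std::pow(st.b1, (double)st.t);
  const double c2 = 1.0 - std::pow(st.b2, (double)st.t);
  for (size_t i = 0; i < params.size(); ++i) {
    if (params[i]->n_elem == 0) continue;
    st.m[i] = st.b1 * st.m[i] + (1.0 - st.b1) * grads[i];
    st.v[i] = st.b2 * st.v[i] + (1.0 - st.b2) * arma::square(grads[i]);
    *params[i] -= st.lr * (st.m[i] / c1) / (arma::sqrt(st.v[i] / c2) + st.eps);
  }
}

static double bce(const arma::rowvec& s, const arma::rowvec& y) {
  const double eps = 1e-7;
  double tot = 0.0;
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    double p = std::min(1.0 - eps, std::max(eps, s[i]));
    tot += -(y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
  }
  return tot / s.n_elem;
}

// [[Rcpp::export]]
List cpp_train_network(IntegerMatrix X, NumericMatrix Xfeat, NumericVector y,
                       List weights, List conf, List hyper,
                       IntegerVector train_idx, IntegerVector val_idx) {
  NetConf cf = conf_from_list(conf);
  NetParams p = params_from_list(weights);
  arma::mat feat = as<arma::mat>(Xfeat);
  arma::vec yy = as<arma::vec>(y);

  const double lr = as<double>(hyper["learning_rate"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int max_epochs = as<int>(hyper["max_epochs"]);
  const int patience = as<int>(hyper["patience"]);

  arma::uvec tr(train_idx.size()), va(val_idx.size());
  for (int i = 0; i < train_idx.size(); ++i) tr[i] = train_idx[i] - 1;
  for (int i = 0; i < val_idx.size(); ++i) va[i] = val_idx[i] - 1;
  const int ntr = tr.n_elem;

  // trainable parameters (running BN moments are not Adam-updated)
  arma::mat b2m(1, 1); b2m(0, 0) = p.b2;
  std::vector<arma::mat*> params;
  // wrap vectors as views is unsafe with arma::vec vs mat; keep explicit mats
  arma::mat bc(p.bc), g1(p.g1), be1(p.be1), b1(p.b1), g2(p.g2), be2(p.be2), w2(p.w2);
  params = { &p.wc, &bc, &g1, &be1, &p.w1, &b1, &g2, &be2, &w2, &b2m };
  AdamState st; st.lr = lr;
  for (auto* q : params) { st.m.emplace_back(arma::size(*q), arma::fill::zeros);
                           st.v.emplace_back(arma::size(*q), arma::fill::zeros); }
  auto sync_vecs = [&]() {
    p.bc = bc.col(0); p.g1 = g1.col(0); p.be1 = be1.col(0);
    p.b1 = b1.col(0); p.g2 = g2.col(0); p.be2 = be2.col(0);
    p.w2 = w2.col(0); p.b2 = b2m(0, 0);
  };

  std::vector<double> log_train, log_val, log_vacc;
  double best_val = R_PosInf;
  int best_epoch = 0, bad = 0;
  List best_weights = params_to_list(p);

  arma::uvec order = tr;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = ntr - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    int nb = 0;
    for (int s0 = 0; s0 < ntr; s0 += batch) {
      const int s1 = std::min(ntr, s0 + batch);
      arma::uvec idx = order.subvec(s0, s1 - 1);
      const int B = idx.n_elem;
      FwdCache c;
      arma::rowvec s = net_forward(X, feat, idx, cf, p, true, &c);
      arma::rowvec yb(B);
      for (int b = 0; b < B; ++b) yb[b] = yy[idx[b]];
      ep_loss += bce(s, yb);
      nb += 1;

      // ---- backward ----
      arma::rowvec dz = (s - yb) / (double)B;
      arma::vec dw2 = c.H2 * dz.t();
      arma::mat db2(1, 1); db2(0, 0) = arma::accu(dz);
      arma::mat dH2 = p.w2 * dz;
      arma::vec dg2(arma::size(p.g2), arma::fill::zeros);
      arma::vec dbe2(arma::size(p.be2), arma::fill::zeros);
      arma::mat dH1 = cf.bn
        ? bn_backward(dH2, c.xhat2, c.istd2, p.g2, dg2, dbe2)
        : dH2;
      dH1 %= arma::conv_to<arma::mat>::from(c.H1 > 0);
      arma::mat dW1 = dH1 * c.Z.t();
      arma::vec db1 = arma::sum(dH1, 1);
      arma::mat dwc(arma::size(p.wc), arma::fill::zeros);
      arma::vec dbc(arma::size(p.bc), arma::fill::zeros);
      arma::vec dg1(arma::size(p.g1), arma::fill::zeros);
      arma::vec dbe1(arma::size(p.be1), arma::fill::zeros);
      if (cf.conv) {
        arma::mat dZ = p.w1.t() * dH1;              // Din x B
        const int Lp = cf.pool ? cf.Lp : cf.L;
        const int F = cf.F, L = cf.L;
        arma::mat dYm;
        if (cf.gpool) {
          dYm.set_size(F, (arma::uword)Lp * B);
          for (int b = 0; b < B; ++b) {
            const double* g = dZ.colptr(b);
            double* d0 = dYm.colptr((arma::uword)b * Lp);
            for (int w = 0; w < Lp; ++w) {
              double* d = d0 + (arma::uword)w * F;
              for (int f = 0; f < F; ++f) d[f] = g[f] / (double)Lp;
            }
          }
        } else {
          dYm = arma::reshape(dZ, F, (arma::uword)Lp * B);
        }
        if (cf.dropout) dYm %= c.mask;
        arma::mat dYc;
        if (cf.bn) dYc = bn_backward(dYm, c.xhat1, c.istd1, p.g1, dg1, dbe1);
        else dYc = dYm;
        arma::mat dYfull;
        if (cf.pool) {
          dYfull.zeros(F, (arma::uword)L * B);
          for (int b = 0; b < B; ++b)
            for (int w = 0; w < cf.Lp; ++w) {
              const arma::uword src = (arma::uword)b * cf.Lp + w;
              const double* dcol = dYc.colptr(src);
              const arma::uword* a = c.amax.colptr(src);
              double* base = dYfull.colptr((arma::uword)b * L +
                                           (arma::uword)w * cf.S2);
              for (int f = 0; f < F; ++f) base[a[f] * F + f] += dcol[f];
            }
        } else {
          dYfull = dYc;
        }
        // ReLU mask of conv output (fused elementwise pass)
        {
          const double* y = c.Yc.memptr();
          double* d = dYfull.memptr();
          const arma::uword n = dYfull.n_elem;
          for (arma::uword i = 0; i < n; ++i) if (y[i] <= 0.0) d[i] = 0.0;
        }
        dbc = arma::sum(dYfull, 1);
        for (int b = 0; b < B; ++b) {
          const int* Xcol = &X(0, idx[b]);
          const double* D0 = dYfull.colptr((arma::uword)b * L);
          for (int m = 0; m < cf.M; ++m) {
            double* Gm = dwc.colptr(m * 4);
            for (int pos = m; pos < L; ++pos) {
              const int cc = Xcol[pos];
              if (cc < 4) {
                const double* dcol = D0 + (arma::uword)(pos - m) * F;
                double* g = Gm + (arma::uword)cc * F;
                for (int f = 0; f < F; ++f) g[f] += dcol[f];
              }
            }
          }
        }
      }
      std::vector<arma::mat> grads = {
        dwc, arma::mat(dbc), arma::mat(dg1), arma::mat(dbe1),
        dW1, arma::mat(db1), arma::mat(dg2), arma::mat(dbe2),
        arma::mat(dw2), db2 };
      adam_step(st, params, grads);
      sync_vecs();
    }
    log_train.push_back(ep_loss / nb);

    // validation in inference mode
    double vloss = NA_REAL, vacc = NA_REAL;
    if (va.n_elem > 0) {
      arma::rowvec vs(va.n_elem), vy(va.n_elem);
      const int chunk = 256;
      for (arma::uword s0 = 0; s0 < va.n_elem; s0 += chunk) {
        const arma::uword s1 = std::min((arma::uword)va.n_elem, s0 + chunk);
        arma::uvec idx = va.subvec(s0, s1 - 1);
        arma::rowvec sc = net_forward(X, feat, idx, cf, p, false, nullptr);
        for (arma::uword i = s0; i < s1; ++i) {
          vs[i] = sc[i - s0];
          vy[i] = yy[va[i]];
        }
      }
      vloss = bce(vs, vy);
      int ok = 0;
      for (arma::uword i = 0; i < va.n_elem; ++i)
        if ((vs[i] > 0.5) == (vy[i] > 0.5)) ok += 1;
      vacc = (double)ok / va.n_elem;
    }
    log_val.push_back(vloss);
    log_vacc.push_back(vacc);

    const double crit = va.n_elem > 0 ? vloss : log_train.back();
    if (crit < best_val) {
      best_val = crit;
      best_epoch = epoch;
      best_weights = params_to_list(p);
      bad = 0;
    } else {
      bad += 1;
      if (bad >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["weights"] = best_weights,
    _["train_loss"] = log_train,
    _["val_loss"] = log_val,
    _["val_acc"] = log_vacc,
    _["best_epoch"] = best_epoch);
}
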