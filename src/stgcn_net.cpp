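// ST-GCN / T-CNN forward, backprop and Adam training loop.
//
// Layout conventions (must match the R reference in model_ref.R):
//  * a sample is an n x M matrix (nodes x time), one input channel;
//  * activations are cubes (n, C, T): slice t is the n x C frame;
//  * block l: temporal conv G0 (Cin -> Cb) -> graph conv Theta (Cb -> Cb)
//    via the per-sample propagation matrix S -> ReLU -> temporal conv G1
//    (Cb -> Cb) -> layer norm (per-sample or per-node scope) with
//    per-channel affine;
//  * head: flatten (node fastest, then channel, then time) -> dense -> sigmoid.
// The T-CNN baseline runs the same stack with S = I (no spatial mixing).

#include <RcppArmadillo.h>
#include <random>
#include <functional>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-5;

struct Block {
  std::vector<mat> G0;   // Kt matrices, Cin x Cb
  mat Theta;             // Cb x Cb
  std::vector<mat> G1;   // Kt matrices, Cb x Cb
  vec g, b;              // layer-norm gain/bias, length Cb
  int Kt = 3, Cin = 1, Cb = 1;
};

struct Net {
  std::vector<Block> blocks;
  vec head_w;
  double head_b = 0.0;
  int n = 0, M = 0, Tf = 0, Clast = 0;
};

struct BlockCache {
  cube in;        // input of the block
  cube Y1;        // after G0
  cube Z;         // after graph conv (pre-ReLU)
  cube R;         // ReLU(Z)
  cube Y2;        // after G1 (pre layer norm)
  cube xhat;      // normalised Y2
  vec m, s;       // per-node layer-norm stats
};

struct Cache {
  std::vector<BlockCache> blocks;
  vec z;          // flattened trunk output
  double logit = 0.0, p = 0.5;
};

static cube tconv(const cube& in, const std::vector<mat>& G) {
  int Kt = (int)G.size();
  int T = (int)in.n_slices, n = (int)in.n_rows;
  int Co = (int)G[0].n_cols;
  int To = T - Kt + 1;
  cube out(n, Co, To, fill::zeros);
  for (int t = 0; t < To; ++t)
    for (int k = 0; k < Kt; ++k)
      out.slice(t) += in.slice(t + k) * G[k];
  return out;
}

static void tconv_backward(const cube& in, const std::vector<mat>& G,
                           const cube& dout, cube& din, std::vector<mat>& dG) {
  int Kt = (int)G.size();
  int To = (int)dout.n_slices;
  din.zeros(in.n_rows, in.n_cols, in.n_slices);
  for (int t = 0; t < To; ++t)
    for (int k = 0; k < Kt; ++k) {
      din.slice(t + k) += dout.slice(t) * G[k].t();
      dG[k] += in.slice(t + k).t() * dout.slice(t);
    }
}

static void block_forward(const Block& B, const mat& S, const cube& in,
                          BlockCache& c, bool sample_ln) {
  c.in = in;
  c.Y1 = tconv(in, B.G0);
  int T1 = (int)c.Y1.n_slices, n = (int)c.Y1.n_rows;
  c.Z.set_size(n, B.Cb, T1);
  for (int t = 0; t < T1; ++t) c.Z.slice(t) = S * c.Y1.slice(t) * B.Theta;
  c.R = c.Z;
  c.R.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.Y2 = tconv(c.R, B.G1);
  int T2 = (int)c.Y2.n_slices;
  c.xhat.set_size(n, B.Cb, T2);
  if (sample_ln) {
    // one normalisation group per sample: cross-node patterns survive
    c.m.set_size(1); c.s.set_size(1);
    double mu = accu(c.Y2) / c.Y2.n_elem;
    double var = 0.0;
    for (size_t q = 0; q < c.Y2.n_elem; ++q) {
      double d = c.Y2(q) - mu; var += d * d;
    }
    var /= c.Y2.n_elem;
    c.m(0) = mu; c.s(0) = std::sqrt(var + LN_EPS);
    c.xhat = (c.Y2 - mu) / c.s(0);
    return;
  }
  // per-node layer norm over the (C, T) slab
  c.m.set_size(n); c.s.set_size(n);
  double G = (double)B.Cb * T2;
  for (int v = 0; v < n; ++v) {
    double mu = 0.0;
    for (int t = 0; t < T2; ++t) mu += accu(c.Y2.slice(t).row(v));
    mu /= G;
    double var = 0.0;
    for (int t = 0; t < T2; ++t) {
      rowvec d = c.Y2.slice(t).row(v) - mu;
      var += accu(d % d);
    }
    var /= G;
    c.m(v) = mu; c.s(v) = std::sqrt(var + LN_EPS);
    for (int t = 0; t < T2; ++t)
      c.xhat.slice(t).row(v) = (c.Y2.slice(t).row(v) - mu) / c.s(v);
  }
}

static cube block_output(const Block& B, const BlockCache& c) {
  cube out = c.xhat;
  int T2 = (int)out.n_slices, n = (int)out.n_rows;
  for (int t = 0; t < T2; ++t)
    for (int v = 0; v < n; ++v)
      out.slice(t).row(v) = out.slice(t).row(v) % B.g.t() + B.b.t();
  return out;
}

static void block_backward(const Block& B, const mat& S, const BlockCache& c,
                           const cube& dout, cube& din, Block& gB,
                           bool sample_ln) {
  int n = (int)c.xhat.n_rows, C = B.Cb, T2 = (int)c.xhat.n_slices;
  double G = (double)C * T2;
  cube dY2(n, C, T2, fill::zeros);
  if (sample_ln) {
    double GS = (double)n * C * T2;
    double s1 = 0.0, s2 = 0.0;
    for (int t = 0; t < T2; ++t)
      for (int v = 0; v < n; ++v) {
        rowvec dy = dout.slice(t).row(v);
        rowvec xh = c.xhat.slice(t).row(v);
        gB.g += (dy % xh).t();
        gB.b += dy.t();
        rowvec dxh = dy % B.g.t();
        s1 += accu(dxh);
        s2 += accu(dxh % xh);
      }
    double m1 = s1 / GS, m2 = s2 / GS;
    for (int t = 0; t < T2; ++t)
      for (int v = 0; v < n; ++v) {
        rowvec dxh = dout.slice(t).row(v) % B.g.t();
        dY2.slice(t).row(v) =
          (dxh - m1 - c.xhat.slice(t).row(v) * m2) / c.s(0);
      }
  } else {
  for (int v = 0; v < n; ++v) {
    rowvec dxh_sum(C, fill::zeros);
    double s1 = 0.0, s2 = 0.0;
    for (int t = 0; t < T2; ++t) {
      rowvec dy = dout.slice(t).row(v);
      rowvec xh = c.xhat.slice(t).row(v);
      gB.g += (dy % xh).t();
      gB.b += dy.t();
      rowvec dxh = dy % B.g.t();
      s1 += accu(dxh);
      s2 += accu(dxh % xh);
    }
    double m1 = s1 / G, m2 = s2 / G;
    for (int t = 0; t < T2; ++t) {
      rowvec dxh = dout.slice(t).row(v) % B.g.t();
      dY2.slice(t).row(v) =
        (dxh - m1 - c.xhat.slice(t).row(v) * m2) / c.s(v);
    }
  }
  }
  // G1 temporal conv backward
  cube dR;
  tconv_backward(c.R, B.G1, dY2, dR, gB.G1);
  // ReLU backward
  int T1 = (int)c.Z.n_slices;
  for (int t = 0; t < T1; ++t)
    dR.slice(t) %= conv_to<mat>::from(c.Z.slice(t) > 0.0);
  // graph conv backward
  cube dY1(n, C, T1);
  for (int t = 0; t < T1; ++t) {
    mat StD = S.t() * dR.slice(t);
    dY1.slice(t) = StD * B.Theta.t();
    gB.Theta += c.Y1.slice(t).t() * StD;
  }
  // G0 temporal conv backward
  tconv_backward(c.in, B.G0, dY1, din, gB.G0);
}

static double forward_sample(const Net& net, const mat& Xs, const mat& S,
                             Cache& c, bool sample_ln) {
  int n = net.n, M = net.M;
  cube x(n, 1, M);
  for (int t = 0; t < M; ++t) x.slice(t).col(0) = Xs.col(t);
  c.blocks.resize(net.blocks.size());
  for (size_t l = 0; l < net.blocks.size(); ++l) {
    block_forward(net.blocks[l], S, x, c.blocks[l], sample_ln);
    x = block_output(net.blocks[l], c.blocks[l]);
  }
  c.z = vectorise(x);
  c.logit = dot(net.head_w, c.z) + net.head_b;
  c.p = 1.0 / (1.0 + std::exp(-c.logit));
  return c.p;
}

static void backward_sample(const Net& net, const mat& S, const Cache& c,
                            double dlogit, Net& grad, bool sample_ln) {
  grad.head_w += dlogit * c.z;
  grad.head_b += dlogit;
  vec dz = dlogit * net.head_w;
  int L = (int)net.blocks.size();
  const BlockCache& last = c.blocks[L - 1];
  cube dout(size(last.xhat));
  std::memcpy(dout.memptr(), dz.memptr(), sizeof(double) * dz.n_elem);
  for (int l = L - 1; l >= 0; --l) {
    cube din;
    block_backward(net.blocks[l], S, c.blocks[l], dout, din,
                   grad.blocks[l], sample_ln);
    dout = din;
  }
}

// ---- parameter flattening (for Adam and the R interface) -------------------

static void for_each_tensor(Net& net,
                            const std::function<void(double*, size_t)>& f) {
  for (auto& B : net.blocks) {
    for (auto& g : B.G0) f(g.memptr(), g.n_elem);
    f(B.Theta.memptr(), B.Theta.n_elem);
    for (auto& g : B.G1) f(g.memptr(), g.n_elem);
    f(B.g.memptr(), B.g.n_elem);
    f(B.b.memptr(), B.b.n_elem);
  }
  f(net.head_w.memptr(), net.head_w.n_elem);
  f(&net.head_b, 1);
}

static size_t net_size(Net& net) {
  size_t n = 0;
  for_each_tensor(net, [&](double*, size_t k) { n += k; });
  return n;
}

static vec pack(Net& net) {
  vec out(net_size(net));
  size_t pos = 0;
  for_each_tensor(net, [&](double* p, size_t k) {
    std::memcpy(out.memptr() + pos, p, sizeof(double) * k);
    pos += k;
  });
  return out;
}

static void unpack(const vec& v, Net& net) {
  size_t pos = 0;
  for_each_tensor(net, [&](double* p, size_t k) {
    std::memcpy(p, v.memptr() + pos, sizeof(double) * k);
    pos += k;
  });
}

// ---- construction ----------------------------------------------------------

static Net make_net(int n, int M, int Kt, const std::vector<int>& widths) {
  Net net;
  net.n = n; net.M = M;
  int Cin = 1, T = M;
  for (int w : widths) {
    Block B;
    B.Kt = Kt; B.Cin = Cin; B.Cb = w;
    B.G0.assign(Kt, mat(Cin, w, fill::zeros));
    B.Theta.zeros(w, w);
    B.G1.assign(Kt, mat(w, w, fill::zeros));
    B.g.ones(w); B.b.zeros(w);
    net.blocks.push_back(B);
    Cin = w;
    T -= 2 * (Kt - 1);
    if (T < 1) Rcpp::stop("configuration error: trunk time length < 1");
  }
  net.Tf = T; net.Clast = Cin;
  net.head_w.zeros((size_t)T * n * Cin);
  return net;
}

static void glorot_init(Net& net, std::mt19937& rng) {
  auto unif = [&](double lim) {
    std::uniform_real_distribution<double> d(-lim, lim);
    return d(rng);
  };
  for (auto& B : net.blocks) {
    double lim0 = std::sqrt(6.0 / (B.Kt * B.Cin + B.Kt * B.Cb));
    for (auto& g : B.G0) g.imbue([&]() { return unif(lim0); });
    double limT = std::sqrt(6.0 / (B.Cb + B.Cb));
    B.Theta.imbue([&]() { return unif(limT); });
    double lim1 = std::sqrt(6.0 / (B.Kt * B.Cb + B.Kt * B.Cb));
    for (auto& g : B.G1) g.imbue([&]() { return unif(lim1); });
    B.g.ones(); B.b.zeros();
  }
  double limH = std::sqrt(6.0 / (net.head_w.n_elem + 1.0));
  net.head_w.imbue([&]() { return unif(limH); });
  net.head_b = 0.0;
}

static Net net_like(const Net& proto) {
  Net g = proto;
  for_each_tensor(g, [](double* p, size_t k) {
    std::memset(p, 0, sizeof(double) * k);
  });
  return g;
}

// ---- R interface helpers ---------------------------------------------------

static std::vector<int> widths_from(const Rcpp::List& config) {
  Rcpp::IntegerVector w = config["channels"];
  return std::vector<int>(w.begin(), w.end());
}

static Net net_from_params(const Rcpp::List& params, const Rcpp::List& config,
                           int n, int M) {
  int Kt = Rcpp::as<int>(config["Kt"]);
  std::vector<int> widths = widths_from(config);
  Net net = make_net(n, M, Kt, widths);
  Rcpp::List blocks = params["blocks"];
  for (size_t l = 0; l < net.blocks.size(); ++l) {
    Rcpp::List bl = blocks[l];
    Block& B = net.blocks[l];
    Rcpp::NumericVector G0 = bl["G0"], G1 = bl["G1"];
    for (int k = 0; k < B.Kt; ++k) {
      for (int i = 0; i < B.Cin; ++i)
        for (int j = 0; j < B.Cb; ++j)
          B.G0[k](i, j) = G0[k + B.Kt * (i + B.Cin * j)];
      for (int i = 0; i < B.Cb; ++i)
        for (int j = 0; j < B.Cb; ++j)
          B.G1[k](i, j) = G1[k + B.Kt * (i + B.Cb * j)];
    }
    B.Theta = Rcpp::as<mat>(bl["Theta"]);
    B.g = Rcpp::as<vec>(bl["ln_gamma"]);
    B.b = Rcpp::as<vec>(bl["ln_beta"]);
  }
  net.head_w = Rcpp::as<vec>(params["head_w"]);
  net.head_b = Rcpp::as<double>(params["head_b"]);
  return net;
}

static Rcpp::List params_to_r(const Net& net) {
  Rcpp::List blocks(net.blocks.size());
  for (size_t l = 0; l < net.blocks.size(); ++l) {
    const Block& B = net.blocks[l];
    Rcpp::NumericVector G0(Rcpp::Dimension(B.Kt, B.Cin, B.Cb));
    Rcpp::NumericVector G1(Rcpp::Dimension(B.Kt, B.Cb, B.Cb));
    for (int k = 0; k < B.Kt; ++k) {
      for (int i = 0; i < B.Cin; ++i)
        for (int j = 0; j < B.Cb; ++j)
          G0[k + B.Kt * (i + B.Cin * j)] = B.G0[k](i, j);
      for (int i = 0; i < B.Cb; ++i)
        for (int j = 0; j < B.Cb; ++j)
          G1[k + B.Kt * (i + B.Cb * j)] = B.G1[k](i, j);
    }
    blocks[l] = Rcpp::List::create(
      Rcpp::Named("G0") = G0,
      Rcpp::Named("Theta") = Rcpp::wrap(B.Theta),
      Rcpp::Named("G1") = G1,
      Rcpp::Named("ln_gamma") = Rcpp::wrap(B.g),
      Rcpp::Named("ln_beta") = Rcpp::wrap(B.b));
  }
  return Rcpp::List::create(
    Rcpp::Named("blocks") = blocks,
    Rcpp::Named("head_w") = Rcpp::wrap(net.head_w),
    Rcpp::Named("head_b") = net.head_b);
}

static const mat& sample_S(const cube& S, int i) {
  static mat dummy;
  return S.n_slices == 1 ? S.slice(0) : S.slice(i);
}

static double bce(double logit, double y) {
  // softplus(logit) - y * logit, numerically stable
  double sp = logit > 0 ? logit + std::log1p(std::exp(-logit))
                        : std::log1p(std::exp(logit));
  return sp - y * logit;
}

// [[Rcpp::export]]
Rcpp::List cpp_stgcn_train(const arma::cube& X, const arma::cube& S,
                           const arma::vec& y,
                           const Rcpp::IntegerVector& train_idx,
                           const Rcpp::IntegerVector& val_idx,
                           const Rcpp::List& config) {
  if (!X.is_finite()) Rcpp::stop("input validation error: non-finite values in X");
  if (!S.is_finite()) Rcpp::stop("input validation error: non-finite values in S");
  int n = (int)X.n_rows, M = (int)X.n_cols;
  int Kt = Rcpp::as<int>(config["Kt"]);
  bool tcnn = Rcpp::as<std::string>(config["variant"]) == "tcnn";
  bool sample_ln = Rcpp::as<std::string>(config["ln_scope"]) == "sample";
  int epochs = Rcpp::as<int>(config["epochs"]);
  int batch = Rcpp::as<int>(config["batch_size"]);
  double lr = Rcpp::as<double>(config["lr"]);
  double b1 = Rcpp::as<double>(config["beta1"]);
  double b2 = Rcpp::as<double>(config["beta2"]);
  double eps = Rcpp::as<double>(config["eps_adam"]);
  unsigned seed = (unsigned)Rcpp::as<int>(config["seed"]);

  Net net = make_net(n, M, Kt, widths_from(config));
  std::mt19937 rng(seed);
  glorot_init(net, rng);

  mat I_n = eye(n, n);
  auto S_of = [&](int i) -> const mat& {
    return tcnn ? I_n : sample_S(S, i);
  };

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  for (auto& i : tr) i -= 1;
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto& i : va) i -= 1;

  vec theta = pack(net);
  vec m(theta.n_elem, fill::zeros), v(theta.n_elem, fill::zeros);
  long step = 0;
  double best_val = datum::inf;
  vec best_theta = theta;
  int checkpoint_epoch = 0;

  mat history(epochs, 5);
  Cache cache;
  Net grad = net_like(net);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double tr_loss = 0.0; int tr_correct = 0;
    for (size_t off = 0; off < tr.size(); off += batch) {
      size_t hi = std::min(off + (size_t)batch, tr.size());
      int bn = (int)(hi - off);
      grad = net_like(net);
      for (size_t q = off; q < hi; ++q) {
        int i = tr[q];
        double p = forward_sample(net, X.slice(i), S_of(i), cache, sample_ln);
        tr_loss += bce(cache.logit, y(i));
        tr_correct += ((p > 0.5) == (y(i) > 0.5));
        backward_sample(net, S_of(i), cache, (p - y(i)) / bn, grad, sample_ln);
      }
      vec g = pack(grad);
      if (!g.is_finite()) Rcpp::stop("training error: non-finite gradient (divergence)");
      ++step;
      m = b1 * m + (1 - b1) * g;
      v = b2 * v + (1 - b2) * square(g);
      vec mhat = m / (1 - std::pow(b1, (double)step));
      vec vhat = v / (1 - std::pow(b2, (double)step));
      theta -= lr * mhat / (sqrt(vhat) + eps);
      unpack(theta, net);
    }
    tr_loss /= tr.size();
    double tr_acc = (double)tr_correct / tr.size();
    double va_loss = NA_REAL, va_acc = NA_REAL;
    if (!va.empty()) {
      va_loss = 0.0; int ok = 0;
      for (int i : va) {
        double p = forward_sample(net, X.slice(i), S_of(i), cache, sample_ln);
        va_loss += bce(cache.logit, y(i));
        ok += ((p > 0.5) == (y(i) > 0.5));
      }
      va_loss /= va.size();
      va_acc = (double)ok / va.size();
      if (va_loss < best_val) {
        best_val = va_loss;
        best_theta = theta;
        checkpoint_epoch = ep + 1;
      }
    }
    history(ep, 0) = ep + 1;
    history(ep, 1) = tr_loss;
    history(ep, 2) = tr_acc;
    history(ep, 3) = va_loss;
    history(ep, 4) = va_acc;
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List final_params = params_to_r(net);
  if (va.empty()) { best_theta = theta; best_val = NA_REAL; checkpoint_epoch = epochs; }
  unpack(best_theta, net);
  Rcpp::List best_params = params_to_r(net);

  return Rcpp::List::create(
    Rcpp::Named("history") = Rcpp::wrap(history),
    Rcpp::Named("params") = best_params,
    Rcpp::Named("final_params") = final_params,
    Rcpp::Named("best_val_loss") = best_val,
    Rcpp::Named("checkpoint_epoch") = checkpoint_epoch);
}

// [[Rcpp::export]]
arma::vec cpp_stgcn_predict(const Rcpp::List& params, const arma::cube& X,
                            const arma::cube& S, const Rcpp::List& config) {
  if (!X.is_finite()) Rcpp::stop("input validation error: non-finite values in X");
  int n = (int)X.n_rows, M = (int)X.n_cols;
  bool tcnn = Rcpp::as<std::string>(config["variant"]) == "tcnn";
  bool sample_ln = Rcpp::as<std::string>(config["ln_scope"]) == "sample";
  Net net = net_from_params(params, config, n, M);
  mat I_n = eye(n, n);
  vec out(X.n_slices);
  Cache cache;
  for (size_t i = 0; i < X.n_slices; ++i) {
    const mat& Si = tcnn ? I_n : sample_S(S, (int)i);
    out(i) = forward_sample(net, X.slice(i), Si, cache, sample_ln);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_stgcn_init(int n, int M, const Rcpp::List& config, int seed) {
  Net net = make_net(n, M, Rcpp::as<int>(config["Kt"]), widths_from(config));
  std::mt19937 rng((unsigned)seed);
  glorot_init(net, rng);
  return params_to_r(net);
}
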