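// Convolutional surrogate: minimal CNN engine (forward, backprop, adagrad)
// for regressing elastic-network eigenvalues from Coulomb matrices.
//
// Architecture (generic in the config, defaults follow the package docs):
//   n_conv_blocks x [conv(kernels, ks x ks, stride 1, same padding) -> ReLU
//                    -> average pool 2x2 stride 2 (floor)]
//   -> flatten -> dropout -> dense(d1) -> ReLU -> dropout
//   -> dense(d2) -> ReLU -> dropout -> linear dense(n_outputs)
// Loss: mean absolute percentage error against strictly positive targets.
// All randomness comes from an internal splitmix64 stream seeded explicitly,
// so training is bit-reproducible for a given (seed, data, config).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // Fisher-Yates
  void shuffle(std::vector<uword>& v) {
    for (uword i = v.size(); i > 1; --i) {
      uword j = static_cast<uword>(unif() * i);
      if (j >= i) j = i - 1;
      std::swap(v[i - 1], v[j]);
    }
  }
};

struct Config {
  int input_size, n_blocks, kernels, ks, n_outputs;
  std::vector<int> dense_units;
  std::vector<int> sizes;      // spatial size entering each block, + final
  int flat_dim;
};

Config parse_config(const Rcpp::List& cfg) {
  Config c;
  c.input_size = Rcpp::as<int>(cfg["input_size"]);
  c.n_blocks   = Rcpp::as<int>(cfg["n_conv_blocks"]);
  c.kernels    = Rcpp::as<int>(cfg["kernels_per_block"]);
  c.ks         = Rcpp::as<int>(cfg["kernel_size"]);
  c.n_outputs  = Rcpp::as<int>(cfg["n_outputs"]);
  c.dense_units = Rcpp::as<std::vector<int>>(cfg["dense_units"]);
  if (c.ks % 2 == 0) Rcpp::stop("kernel_size must be odd");
  int s = c.input_size;
  c.sizes.push_back(s);
  for (int b = 0; b < c.n_blocks; ++b) {
    s = s / 2;                               // pool 2x2, floor
    if (s < 1) Rcpp::stop("input too small for %d conv blocks", c.n_blocks);
    c.sizes.push_back(s);
  }
  c.flat_dim = s * s * c.kernels;
  return c;
}

struct Net {
  Config cfg;
  std::vector<mat> convW;   // (ks*ks*cin) x cout
  std::vector<vec> convb;
  std::vector<mat> denseW;  // in x out
  std::vector<vec> denseb;
};

Net unpack(const Rcpp::List& weights, const Rcpp::List& cfg) {
  Net net;
  net.cfg = parse_config(cfg);
  Rcpp::List conv = weights["conv"], dense = weights["dense"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List layer = conv[i];
    net.convW.push_back(Rcpp::as<mat>(layer["W"]));
    net.convb.push_back(Rcpp::as<vec>(layer["b"]));
  }
  for (int i = 0; i < dense.size(); ++i) {
    Rcpp::List layer = dense[i];
    net.denseW.push_back(Rcpp::as<mat>(layer["W"]));
    net.denseb.push_back(Rcpp::as<vec>(layer["b"]));
  }
  if ((int)net.convW.size() != net.cfg.n_blocks)
    Rcpp::stop("weights have %d conv layers, config says %d",
               (int)net.convW.size(), net.cfg.n_blocks);
  return net;
}

Rcpp::List pack(const Net& net) {
  Rcpp::List conv(net.convW.size()), dense(net.denseW.size());
  for (size_t i = 0; i < net.convW.size(); ++i)
    conv[i] = Rcpp::List::create(Rcpp::Named("W") = net.convW[i],
                                 Rcpp::Named("b") = net.convb[i]);
  for (size_t i = 0; i < net.denseW.size(); ++i)
    dense[i] = Rcpp::List::create(Rcpp::Named("W") = net.denseW[i],
                                  Rcpp::Named("b") = net.denseb[i]);
  return Rcpp::List::create(Rcpp::Named("conv") = conv,
                            Rcpp::Named("dense") = dense);
}

// im2col for stride-1 same-padding convolution: output (h*w) x (ks*ks*cin),
// row r = i + j*h for output pixel (i, j); column c*ks*ks + ki + kj*ks.
void im2col(const cube& in, int ks, mat& out) {
  const int h = in.n_rows, w = in.n_cols, cin = in.n_slices, p = ks / 2;
  out.zeros(h * w, ks * ks * cin);
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < ks; ++kj)
      for (int ki = 0; ki < ks; ++ki) {
        const int di = ki - p, dj = kj - p;
        const int i0 = std::max(0, -di), i1 = std::min(h - 1, h - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(w - 1, w - 1 - dj);
        if (i0 > i1 || j0 > j1) continue;
        mat col(out.colptr(c * ks * ks + kj * ks + ki), h, w, false, true);
        col.submat(i0, j0, i1, j1) =
          in.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
      }
}

// scatter-add transpose of im2col
void col2im(const mat& cols, int ks, cube& din) {
  const int h = din.n_rows, w = din.n_cols, cin = din.n_slices, p = ks / 2;
  din.zeros();
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < ks; ++kj)
      for (int ki = 0; ki < ks; ++ki) {
        const int di = ki - p, dj = kj - p;
        const int i0 = std::max(0, -di), i1 = std::min(h - 1, h - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(w - 1, w - 1 - dj);
        if (i0 > i1 || j0 > j1) continue;
        const mat col(const_cast<double*>(cols.colptr(c * ks * ks +
                                                      kj * ks + ki)),
                      h, w, false, true);
        din.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
          col.submat(i0, j0, i1, j1);
      }
}

void avgpool(const cube& in, cube& out) {
  const int h2 = in.n_rows / 2, w2 = in.n_cols / 2, ch = in.n_slices;
  out.set_size(h2, w2, ch);
  for (int c = 0; c < ch; ++c)
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h2; ++i)
        out(i, j, c) = 0.25 * (in(2 * i, 2 * j, c) + in(2 * i + 1, 2 * j, c) +
                               in(2 * i, 2 * j + 1, c) +
                               in(2 * i + 1, 2 * j + 1, c));
}

void avgpool_back(const cube& dout, cube& din) {
  din.zeros();
  const int h2 = dout.n_rows, w2 = dout.n_cols, ch = dout.n_slices;
  for (int c = 0; c < ch; ++c)
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h2; ++i) {
        const double g = 0.25 * dout(i, j, c);
        din(2 * i, 2 * j, c) += g;
        din(2 * i + 1, 2 * j, c) += g;
        din(2 * i, 2 * j + 1, c) += g;
        din(2 * i + 1, 2 * j + 1, c) += g;
      }
}

// per-sample forward workspace (reused across samples)
struct Workspace {
  std::vector<cube> block_in;    // input cube of each block
  std::vector<mat>  cols;        // im2col of each block input
  std::vector<cube> preact;      // conv output before ReLU
  std::vector<cube> pooled;      // block output
  vec flat, flat_drop;
  std::vector<vec> dense_pre, dense_act, dense_drop;
  std::vector<vec> drop_mask;    // inverted dropout masks (3 of them)
};

vec forward(const Net& net, const mat& x, Workspace& ws,
            double dropout, XRng* rng) {
  const Config& c = net.cfg;
  const int nb = c.n_blocks;
  ws.block_in.resize(nb); ws.cols.resize(nb);
  ws.preact.resize(nb); ws.pooled.resize(nb);
  cube cur(x.n_rows, x.n_cols, 1);
  cur.slice(0) = x;
  for (int b = 0; b < nb; ++b) {
    ws.block_in[b] = cur;
    im2col(cur, c.ks, ws.cols[b]);
    mat z = ws.cols[b] * net.convW[b];
    z.each_row() += net.convb[b].t();
    cube zc(z.memptr(), cur.n_rows, cur.n_cols, c.kernels);
    ws.preact[b] = zc;
    cube act = zc;
    act.transform([](double v) { return v > 0 ? v : 0.0; });
    avgpool(act, ws.pooled[b]);
    cur = ws.pooled[b];
  }
  ws.flat = vectorise(cur);
  const int ndense = net.denseW.size();
  ws.dense_pre.resize(ndense); ws.dense_act.resize(ndense);
  ws.dense_drop.resize(ndense); ws.drop_mask.assign(ndense, vec());
  auto make_mask = [&](int len) {
    vec m(len, fill::ones);
    if (dropout > 0 && rng) {
      const double keep = 1.0 - dropout;
      for (int i = 0; i < len; ++i)
        m[i] = (rng->unif() < keep) ? 1.0 / keep : 0.0;
    }
    return m;
  };
  // dropout before the first dense layer
  ws.drop_mask[0] = make_mask(ws.flat.n_elem);
  ws.flat_drop = ws.flat % ws.drop_mask[0];
  vec h = ws.flat_drop;
  for (int l = 0; l < ndense; ++l) {
    ws.dense_pre[l] = net.denseW[l].t() * h + net.denseb[l];
    if (l < ndense - 1) {                       // hidden: ReLU + dropout
      ws.dense_act[l] = ws.dense_pre[l];
      ws.dense_act[l].transform([](double v) { return v > 0 ? v : 0.0; });
      if (l + 1 < ndense) {
        vec m = make_mask(ws.dense_act[l].n_elem);
        if ((int)ws.drop_mask.size() <= l + 1) ws.drop_mask.resize(l + 2);
        ws.drop_mask[l + 1] = m;
        ws.dense_drop[l] = ws.dense_act[l] % m;
      } else {
        ws.dense_drop[l] = ws.dense_act[l];
      }
      h = ws.dense_drop[l];
    }
  }
  return ws.dense_pre[ndense - 1];              // linear output
}

struct Grads {
  std::vector<mat> convW; std::vector<vec> convb;
  std::vector<mat> denseW; std::vector<vec> denseb;
  void zero_like(const Net& net) {
    convW.clear(); convb.clear(); denseW.clear(); denseb.clear();
    for (auto& w : net.convW) convW.push_back(zeros<mat>(size(w)));
    for (auto& b : net.convb) convb.push_back(zeros<vec>(size(b)));
    for (auto& w : net.denseW) denseW.push_back(zeros<mat>(size(w)));
    for (auto& b : net.denseb) denseb.push_back(zeros<vec>(size(b)));
  }
};

// backprop one sample given d(loss)/d(output); accumulates into g
void backward(const Net& net, Workspace& ws, const vec& dout, Grads& g) {
  const Config& c = net.cfg;
  const int ndense = net.denseW.size();
  vec delta = dout;
  for (int l = ndense - 1; l >= 0; --l) {
    const vec& in = (l == 0) ? ws.flat_drop : ws.dense_drop[l - 1];
    g.denseW[l] += in * delta.t();
    g.denseb[l] += delta;
    vec dIn = net.denseW[l] * delta;
    if (l == 0) {
      delta = dIn % ws.drop_mask[0];
    } else {
      dIn %= ws.drop_mask[l];                      // dropout mask
      // ReLU of the previous hidden layer
      const vec& pre = ws.dense_pre[l - 1];
      for (uword i = 0; i < dIn.n_elem; ++i)
        if (pre[i] <= 0) dIn[i] = 0;
      delta = dIn;
    }
  }
  // delta is now gradient wrt the flatten vector
  const int nb = c.n_blocks;
  cube dcur(ws.pooled[nb - 1].n_rows, ws.pooled[nb - 1].n_cols, c.kernels);
  std::memcpy(dcur.memptr(), delta.memptr(), delta.n_elem * sizeof(double));
  for (int b = nb - 1; b >= 0; --b) {
    cube dact(ws.preact[b].n_rows, ws.preact[b].n_cols, c.kernels);
    avgpool_back(dcur, dact);
    // ReLU
    for (uword i = 0; i < dact.n_elem; ++i)
      if (ws.preact[b].memptr()[i] <= 0) dact.memptr()[i] = 0;
    mat dz(dact.memptr(), dact.n_rows * dact.n_cols, c.kernels, false, true);
    g.convW[b] += ws.cols[b].t() * dz;
    g.convb[b] += sum(dz, 0).t();
    if (b > 0) {
      mat dcols = dz * net.convW[b].t();
      dcur.set_size(ws.block_in[b].n_rows, ws.block_in[b].n_cols,
                    ws.block_in[b].n_slices);
      col2im(dcols, c.ks, dcur);
    }
  }
}

// MAPE of one sample (percent); dgrad gets d(loss)/d(pred) for unit weight
double sample_mape(const vec& pred, const vec& truth, vec* dgrad) {
  const int n = truth.n_elem;
  double loss = 0;
  if (dgrad) dgrad->zeros(n);
  for (int i = 0; i < n; ++i) {
    if (truth[i] == 0) Rcpp::stop("zero true eigenvalue in MAPE");
    const double r = (pred[i] - truth[i]) / std::abs(truth[i]);
    loss += std::abs(r);
    if (dgrad)
      (*dgrad)[i] = (r > 0 ? 1.0 : (r < 0 ? -1.0 : 0.0)) /
        std::abs(truth[i]);
  }
  loss *= 100.0 / n;
  if (dgrad) *dgrad *= 100.0 / n;
  return loss;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_cnn_init(Rcpp::List cfg, int seed) {
  Config c = parse_config(cfg);
  XRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  Net net; net.cfg = c;
  auto glorot = [&](int rows, int cols, double fan_in, double fan_out) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    mat w(rows, cols);
    for (uword i = 0; i < w.n_elem; ++i)
      w.memptr()[i] = (2.0 * rng.unif() - 1.0) * lim;
    return w;
  };
  int cin = 1;
  for (int b = 0; b < c.n_blocks; ++b) {
    net.convW.push_back(glorot(c.ks * c.ks * cin, c.kernels,
                               c.ks * c.ks * cin, c.ks * c.ks * c.kernels));
    net.convb.push_back(zeros<vec>(c.kernels));
    cin = c.kernels;
  }
  std::vector<int> dims;
  dims.push_back(c.flat_dim);
  for (int u : c.dense_units) dims.push_back(u);
  dims.push_back(c.n_outputs);
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    net.denseW.push_back(glorot(dims[l], dims[l + 1], dims[l], dims[l + 1]));
    net.denseb.push_back(zeros<vec>(dims[l + 1]));
  }
  return pack(net);
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_cnn_predict(Rcpp::List weights, arma::cube x, Rcpp::List cfg) {
  Net net = unpack(weights, cfg);
  const int n = x.n_slices;
  mat out(n, net.cfg.n_outputs);
  Workspace ws;
  for (int s = 0; s < n; ++s)
    out.row(s) = forward(net, x.slice(s), ws, 0.0, nullptr).t();
  return out;
}

//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_cnn_loss_grad(Rcpp::List weights, arma::mat x, arma::vec y,
                             Rcpp::List cfg) {
  Net net = unpack(weights, cfg);
  Workspace ws;
  vec pred = forward(net, x, ws, 0.0, nullptr);
  vec dgrad;
  double loss = sample_mape(pred, y, &dgrad);
  Grads g; g.zero_like(net);
  backward(net, ws, dgrad, g);
  Net gn; gn.cfg = net.cfg;
  gn.convW = g.convW; gn.convb = g.convb;
  gn.denseW = g.denseW; gn.denseb = g.denseb;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(gn));
}

//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List weights, arma::cube x, arma::mat y,
                         Rcpp::Nullable<arma::cube> x_eval,
                         Rcpp::Nullable<arma::mat> y_eval,
                         Rcpp::List cfg, int epochs, int batch_size,
                         double lr, double dropout, int seed,
                         bool verbose) {
  Net net = unpack(weights, cfg);
  const int n = x.n_slices;
  if ((int)y.n_rows != net.cfg.n_outputs || (int)y.n_cols != n)
    Rcpp::stop("targets must be n_outputs x n_samples");
  const bool has_eval = x_eval.isNotNull() && y_eval.isNotNull();
  cube xe; mat ye;
  if (has_eval) {
    xe = Rcpp::as<cube>(x_eval.get());
    ye = Rcpp::as<mat>(y_eval.get());
  }

  XRng rng(static_cast<uint64_t>(seed) * 0x9E3779B9ULL + 12345ULL);
  Grads g, G;                 // batch gradient and adagrad accumulator
  G.zero_like(net);
  const double eps = 1e-7;
  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  vec hist_train(epochs, fill::zeros), hist_eval(epochs, fill::zeros);
  Workspace ws;

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(order);
    double ep_loss = 0;
    int done = 0;
    while (done < n) {
      const int bs = std::min(batch_size, n - done);
      g.zero_like(net);
      for (int s = 0; s < bs; ++s) {
        const uword idx = order[done + s];
        vec pred = forward(net, x.slice(idx), ws, dropout, &rng);
        vec dgrad;
        const double l = sample_mape(pred, y.col(idx), &dgrad);
        if (!std::isfinite(l))
          Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
        ep_loss += l;
        dgrad /= bs;
        backward(net, ws, dgrad, g);
      }
      // adagrad update
      auto upd = [&](mat& w, mat& acc, const mat& grad) {
        acc += square(grad);
        w -= lr * grad / (sqrt(acc) + eps);
      };
      auto updv = [&](vec& w, vec& acc, const vec& grad) {
        acc += square(grad);
        w -= lr * grad / (sqrt(acc) + eps);
      };
      for (size_t i = 0; i < net.convW.size(); ++i) {
        upd(net.convW[i], G.convW[i], g.convW[i]);
        updv(net.convb[i], G.convb[i], g.convb[i]);
      }
      for (size_t i = 0; i < net.denseW.size(); ++i) {
        upd(net.denseW[i], G.denseW[i], g.denseW[i]);
        updv(net.denseb[i], G.denseb[i], g.denseb[i]);
      }
      done += bs;
      Rcpp::checkUserInterrupt();
    }
    hist_train[ep] = ep_loss / n;
    if (has_eval) {
      double el = 0;
      for (uword s = 0; s < xe.n_slices; ++s) {
        vec pred = forward(net, xe.slice(s), ws, 0.0, nullptr);
        el += sample_mape(pred, ye.col(s), nullptr);
      }
      hist_eval[ep] = el / xe.n_slices;
    } else {
      hist_eval[ep] = datum::nan;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << " train MAPE " << hist_train[ep]
                  << (has_eval ? " eval MAPE " : "")
                  << (has_eval ? std::to_string(hist_eval[ep]) : "")
                  << std::endl;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = pack(net),
                            Rcpp::Named("train_mape") = hist_train,
                            Rcpp::Named("eval_mape") = hist_eval);
}
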