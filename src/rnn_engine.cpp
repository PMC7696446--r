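// Recurrent forecasting engine: forward pass and backpropagation through
// time for simple RNN / GRU / LSTM stacks (1-2 layers, optionally
// bidirectional), a dense hidden layer and a scalar linear output, trained
// by minibatch gradient descent with RMSprop or Adamax.
//
// Weight list layout (positional, built by init_weights() on the R side):
//   for layer in 1..nlayers: for dir in 1..(bidir ? 2 : 1): W, U, b
//   then Wd1, bd1, Wd2, bd2
// Gate column blocks: RNN [h]; GRU [z r h]; LSTM [i f g o].
// Activation `act` applies to the state (RNN), candidate (GRU) and cell
// input/output transform (LSTM); gate activations are always logistic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int CELL_RNN = 0, CELL_GRU = 1, CELL_LSTM = 2;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static inline mat actf(const mat& x, int act) {
  return act == 1 ? mat(arma::tanh(x)) : x;
}
// derivative expressed through the activated value h
static inline mat actdf_h(const mat& h, int act) {
  if (act == 1) return 1.0 - arma::square(h);
  return arma::ones<mat>(h.n_rows, h.n_cols);
}

struct NetCfg {
  int cell, nlayers, units, act, dense_act;
  bool bidir;
  int ndir() const { return bidir ? 2 : 1; }
  int gates() const { return cell == CELL_GRU ? 3 : (cell == CELL_LSTM ? 4 : 1); }
};

// per (layer, dir) forward cache, processed-time order
struct DirCache {
  std::vector<mat> xs;          // inputs at each processed step (B x I)
  std::vector<mat> H;           // states (B x U)
  std::vector<mat> Z, R, HH;    // GRU gates/candidate
  std::vector<mat> I, F, G, O, C, HC;  // LSTM gates, cell, tanh(cell)
};

struct FwdCache {
  std::vector<DirCache> dirs;   // nlayers * ndir entries
  mat feat;                     // B x F features into dense layers
  mat d1;                       // B x dh activated dense hidden
  mat yhat;                     // B x 1
};

static std::vector<mat> weights_from_list(const List& wl) {
  std::vector<mat> w;
  w.reserve(wl.size());
  for (int i = 0; i < wl.size(); ++i) w.push_back(as<mat>(wl[i]));
  return w;
}

static List weights_to_list(const std::vector<mat>& w, const List& tmpl) {
  List out(w.size());
  for (size_t i = 0; i < w.size(); ++i) out[i] = wrap(w[i]);
  out.attr("names") = tmpl.attr("names");
  return out;
}

// run one recurrent direction over a processed-order input sequence
static void run_dir(const NetCfg& cfg, DirCache& dc,
                    const std::vector<mat>& seq, bool reverse,
                    const mat& W, const mat& U, const mat& b) {
  const int L = (int)seq.size();
  const int B = (int)seq[0].n_rows;
  const int Un = cfg.units;
  mat h = arma::zeros<mat>(B, Un);
  mat c = arma::zeros<mat>(B, Un);
  mat bb = arma::repmat(b, B, 1);
  dc.xs.resize(L); dc.H.resize(L);
  if (cfg.cell == CELL_GRU) { dc.Z.resize(L); dc.R.resize(L); dc.HH.resize(L); }
  if (cfg.cell == CELL_LSTM) {
    dc.I.resize(L); dc.F.resize(L); dc.G.resize(L); dc.O.resize(L);
    dc.C.resize(L); dc.HC.resize(L);
  }
  for (int t = 0; t < L; ++t) {
    const mat& x = seq[reverse ? (L - 1 - t) : t];
    dc.xs[t] = x;
    if (cfg.cell == CELL_RNN) {
      h = actf(x * W + h * U + bb, cfg.act);
    } else if (cfg.cell == CELL_GRU) {
      mat pre_x = x * W + bb;          // B x 3U
      mat z = sigm(pre_x.cols(0, Un - 1) + h * U.cols(0, Un - 1));
      mat r = sigm(pre_x.cols(Un, 2 * Un - 1) + h * U.cols(Un, 2 * Un - 1));
      mat hh = actf(pre_x.cols(2 * Un, 3 * Un - 1) +
                    (r % h) * U.cols(2 * Un, 3 * Un - 1), cfg.act);
      dc.Z[t] = z; dc.R[t] = r; dc.HH[t] = hh;
      h = (1.0 - z) % h + z % hh;
    } else {  // LSTM
      mat pre = x * W + h * U + bb;    // B x 4U
      mat i = sigm(pre.cols(0, Un - 1));
      mat f = sigm(pre.cols(Un, 2 * Un - 1));
      mat g = actf(pre.cols(2 * Un, 3 * Un - 1), cfg.act);
      mat o = sigm(pre.cols(3 * Un, 4 * Un - 1));
      c = f % c + i % g;
      mat hc = actf(c, cfg.act);
      dc.I[t] = i; dc.F[t] = f; dc.G[t] = g; dc.O[t] = o;
      dc.C[t] = c; dc.HC[t] = hc;
      h = o % hc;
    }
    dc.H[t] = h;
  }
}

// full forward pass over a batch; Xb is B x L (single input feature)
static void forward(const NetCfg& cfg, const std::vector<mat>& w,
                    const mat& Xb, FwdCache& fc) {
  const int L = (int)Xb.n_cols, B = (int)Xb.n_rows;
  const int nd = cfg.ndir();
  fc.dirs.assign(cfg.nlayers * nd, DirCache());
  std::vector<mat> seq(L);
  for (int t = 0; t < L; ++t) seq[t] = Xb.col(t);

  int wi = 0;
  for (int l = 0; l < cfg.nlayers; ++l) {
    for (int d = 0; d < nd; ++d) {
      DirCache& dc = fc.dirs[l * nd + d];
      run_dir(cfg, dc, seq, d == 1, w[wi], w[wi + 1], w[wi + 2]);
      wi += 3;
    }
    if (l < cfg.nlayers - 1) {
      // lower layer returns its state sequence, aligned to original time
      std::vector<mat> nseq(L);
      for (int t = 0; t < L; ++t) {
        if (nd == 1) nseq[t] = fc.dirs[l * nd].H[t];
        else nseq[t] = arma::join_rows(fc.dirs[l * nd].H[t],
                                       fc.dirs[l * nd + 1].H[L - 1 - t]);
      }
      seq = nseq;
    }
  }
  // features: each direction's final processed state of the top layer
  int top = (cfg.nlayers - 1) * nd;
  fc.feat = fc.dirs[top].H[L - 1];
  if (nd == 2) fc.feat = arma::join_rows(fc.feat, fc.dirs[top + 1].H[L - 1]);

  const mat& Wd1 = w[wi], &bd1 = w[wi + 1], &Wd2 = w[wi + 2], &bd2 = w[wi + 3];
  mat d1 = fc.feat * Wd1 + arma::repmat(bd1, B, 1);
  if (cfg.dense_act == 1) d1 = arma::clamp(d1, 0.0, arma::datum::inf);
  fc.d1 = d1;
  fc.yhat = d1 * Wd2 + arma::repmat(bd2, B, 1);
}

// BPTT for one direction; dh_seq holds processed-order gradients flowing
// into each step's state from above; returns input grads in processed order
static void backward_dir(const NetCfg& cfg, const DirCache& dc,
                         std::vector<mat>& dh_seq,
                         const mat& W, const mat& U,
                         mat& gW, mat& gU, mat& gb,
                         std::vector<mat>& dx) {
  const int L = (int)dc.H.size();
  const int B = (int)dc.H[0].n_rows;
  const int Un = cfg.units;
  mat dh_next = arma::zeros<mat>(B, Un);
  mat dc_next = arma::zeros<mat>(B, Un);
  dx.assign(L, mat());
  for (int t = L - 1; t >= 0; --t) {
    mat dh = dh_seq[t] + dh_next;
    mat h_prev = (t == 0) ? arma::zeros<mat>(B, Un) : dc.H[t - 1];
    if (cfg.cell == CELL_RNN) {
      mat da = dh % actdf_h(dc.H[t], cfg.act);
      gW += dc.xs[t].t() * da;
      gU += h_prev.t() * da;
      gb += arma::sum(da, 0);
      dh_next = da * U.t();
      dx[t] = da * W.t();
    } else if (cfg.cell == CELL_GRU) {
      const mat &z = dc.Z[t], &r = dc.R[t], &hh = dc.HH[t];
      mat dz = dh % (hh - h_prev);
      mat dhh = dh % z;
      mat dh_prev = dh % (1.0 - z);
      mat da_h = dhh % actdf_h(hh, cfg.act);
      mat drh = da_h * U.cols(2 * Un, 3 * Un - 1).t();
      mat dr = drh % h_prev;
      dh_prev += drh % r;
      mat da_z = dz % z % (1.0 - z);
      mat da_r = dr % r % (1.0 - r);
      gW.cols(0, Un - 1)          += dc.xs[t].t() * da_z;
      gW.cols(Un, 2 * Un - 1)     += dc.xs[t].t() * da_r;
      gW.cols(2 * Un, 3 * Un - 1) += dc.xs[t].t() * da_h;
      gU.cols(0, Un - 1)          += h_prev.t() * da_z;
      gU.cols(Un, 2 * Un - 1)     += h_prev.t() * da_r;
      gU.cols(2 * Un, 3 * Un - 1) += (r % h_prev).t() * da_h;
      gb.cols(0, Un - 1)          += arma::sum(da_z, 0);
      gb.cols(Un, 2 * Un - 1)     += arma::sum(da_r, 0);
      gb.cols(2 * Un, 3 * Un - 1) += arma::sum(da_h, 0);
      dh_prev += da_z * U.cols(0, Un - 1).t() + da_r * U.cols(Un, 2 * Un - 1).t();
      dx[t] = da_z * W.cols(0, Un - 1).t() +
              da_r * W.cols(Un, 2 * Un - 1).t() +
              da_h * W.cols(2 * Un, 3 * Un - 1).t();
      dh_next = dh_prev;
    } else {  // LSTM
      const mat &i = dc.I[t], &f = dc.F[t], &g = dc.G[t], &o = dc.O[t];
      const mat &hc = dc.HC[t];
      mat c_prev = (t == 0) ? arma::zeros<mat>(B, Un) : dc.C[t - 1];
      mat do_ = dh % hc;
      mat dcell = dc_next + dh % o % actdf_h(hc, cfg.act);
      mat di = dcell % g;
      mat dg = dcell % i;
      mat df = dcell % c_prev;
      dc_next = dcell % f;
      mat da_i = di % i % (1.0 - i);
      mat da_f = df % f % (1.0 - f);
      mat da_g = dg % actdf_h(g, cfg.act);
      mat da_o = do_ % o % (1.0 - o);
      mat da = arma::join_rows(arma::join_rows(da_i, da_f),
                               arma::join_rows(da_g, da_o));
      gW += dc.xs[t].t() * da;
      gU += h_prev.t() * da;
      gb += arma::sum(da, 0);
      dh_next = da * U.t();
      dx[t] = da * W.t();
    }
  }
}

// forward + backward over one batch; returns sum of squared errors and,
// if grads is non-null, accumulates parameter gradients of the batch-mean
// MSE into *grads (zeroed here)
static double forward_backward(const NetCfg& cfg, const std::vector<mat>& w,
                               const mat& Xb, const vec& yb,
                               std::vector<mat>* grads, vec* pred_out) {
  FwdCache fc;
  forward(cfg, w, Xb, fc);
  const int B = (int)Xb.n_rows, L = (int)Xb.n_cols;
  vec resid = fc.yhat.col(0) - yb;
  double sse = arma::dot(resid, resid);
  if (pred_out) *pred_out = fc.yhat.col(0);
  if (!grads) return sse;

  std::vector<mat>& g = *grads;
  g.assign(w.size(), mat());
  for (size_t i = 0; i < w.size(); ++i) g[i] = arma::zeros<mat>(w[i].n_rows, w[i].n_cols);

  const int nd = cfg.ndir();
  int wi_dense = cfg.nlayers * nd * 3;
  const mat& Wd1 = w[wi_dense], &Wd2 = w[wi_dense + 2];

  mat dyhat = 2.0 * mat(resid) / (double)B;            // B x 1
  g[wi_dense + 2] = fc.d1.t() * dyhat;                 // Wd2
  g[wi_dense + 3] = arma::sum(dyhat, 0);               // bd2
  mat dd1 = dyhat * Wd2.t();
  if (cfg.dense_act == 1) dd1 = dd1 % arma::conv_to<mat>::from(fc.d1 > 0);
  g[wi_dense]     = fc.feat.t() * dd1;                 // Wd1
  g[wi_dense + 1] = arma::sum(dd1, 0);                 // bd1
  mat dfeat = dd1 * Wd1.t();

  // gradients flowing into each (layer, dir) state sequence, processed order
  const int Un = cfg.units;
  std::vector<std::vector<mat>> dh(cfg.nlayers * nd);
  mat zB = arma::zeros<mat>(B, Un);
  for (int l = 0; l < cfg.nlayers; ++l)
    for (int d = 0; d < nd; ++d)
      dh[l * nd + d].assign(L, zB);
  int top = (cfg.nlayers - 1) * nd;
  dh[top][L - 1] += dfeat.cols(0, Un - 1);
  if (nd == 2) dh[top + 1][L - 1] += dfeat.cols(Un, 2 * Un - 1);

  for (int l = cfg.nlayers - 1; l >= 0; --l) {
    std::vector<mat> dseq;  // grads wrt this layer's input, original time
    for (int d = 0; d < nd; ++d) {
      int wi = (l * nd + d) * 3;
      std::vector<mat> dx;
      backward_dir(cfg, fc.dirs[l * nd + d], dh[l * nd + d],
                   w[wi], w[wi + 1], g[wi], g[wi + 1], g[wi + 2], dx);
      if (l == 0) continue;  // input grads of layer 1 are not needed
      if (dseq.empty()) {
        int I = (int)dx[0].n_cols;
        dseq.assign(L, arma::zeros<mat>(B, I));
      }
      for (int t = 0; t < L; ++t) dseq[d == 0 ? t : (L - 1 - t)] += dx[t];
    }
    if (l > 0) {
      // route to the lower layer's per-direction state grads
      for (int t = 0; t < L; ++t) {
        dh[(l - 1) * nd][t] += dseq[t].cols(0, Un - 1);
        if (nd == 2)
          dh[(l - 1) * nd + 1][L - 1 - t] += dseq[t].cols(Un, 2 * Un - 1);
      }
    }
  }
  return sse;
}

static NetCfg make_cfg(int cell, int nlayers, bool bidir, int units,
                       int act, int dense_act) {
  NetCfg cfg;
  cfg.cell = cell; cfg.nlayers = nlayers; cfg.bidir = bidir;
  cfg.units = units; cfg.act = act; cfg.dense_act = dense_act;
  return cfg;
}

// [[Rcpp::export]]
NumericVector rnn_predict_cpp(List weights, const arma::mat& X,
                              int cell, int nlayers, bool bidir, int units,
                              int act, int dense_act) {
  NetCfg cfg = make_cfg(cell, nlayers, bidir, units, act, dense_act);
  std::vector<mat> w = weights_from_list(weights);
  FwdCache fc;
  forward(cfg, w, X, fc);
  return wrap(fc.yhat.col(0));
}

// [[Rcpp::export]]
List rnn_loss_grad_cpp(List weights, const arma::mat& X, const arma::vec& y,
                       int cell, int nlayers, bool bidir, int units,
                       int act, int dense_act) {
  NetCfg cfg = make_cfg(cell, nlayers, bidir, units, act, dense_act);
  std::vector<mat> w = weights_from_list(weights);
  std::vector<mat> g;
  double sse = forward_backward(cfg, w, X, y, &g, nullptr);
  return List::create(_["loss"] = sse / (double)X.n_rows,
                      _["grads"] = weights_to_list(g, weights));
}

// [[Rcpp::export]]
List rnn_fit_cpp(List weights, const arma::mat& X, const arma::vec& y,
                 int cell, int nlayers, bool bidir, int units,
                 int act, int dense_act,
                 int optimizer,  // 0 = rmsprop, 1 = adamax
                 double lr, int batch_size, int epochs,
                 const IntegerMatrix& order) {  // epochs x n, 1-based
  NetCfg cfg = make_cfg(cell, nlayers, bidir, units, act, dense_act);
  std::vector<mat> w = weights_from_list(weights);
  const int n = (int)X.n_rows;
  const double rho = 0.9, eps = 1e-7, beta1 = 0.9, beta2 = 0.999;

  std::vector<mat> v(w.size()), m(w.size()), u(w.size());
  for (size_t i = 0; i < w.size(); ++i) {
    v[i] = arma::zeros<mat>(w[i].n_rows, w[i].n_cols);
    if (optimizer == 1) { m[i] = v[i]; u[i] = v[i]; }
  }

  NumericVector history(epochs);
  std::vector<mat> g;
  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    double sse_epoch = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n) - 1;
      int B = end - start + 1;
      mat Xb(B, X.n_cols);
      vec yb(B);
      for (int k = 0; k < B; ++k) {
        int idx = order(e, start + k) - 1;
        Xb.row(k) = X.row(idx);
        yb(k) = y(idx);
      }
      sse_epoch += forward_backward(cfg, w, Xb, yb, &g, nullptr);
      ++step;
      for (size_t i = 0; i < w.size(); ++i) {
        if (optimizer == 0) {
          v[i] = rho * v[i] + (1.0 - rho) * arma::square(g[i]);
          w[i] -= lr * g[i] / (arma::sqrt(v[i]) + eps);
        } else {
          m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
          u[i] = arma::max(beta2 * u[i], arma::abs(g[i]));
          double lr_t = lr / (1.0 - std::pow(beta1, (double)step));
          w[i] -= lr_t * m[i] / (u[i] + eps);
        }
        if (!w[i].is_finite())
          stop("training diverged (non-finite weights); lower the learning rate or check input scaling");
      }
    }
    history[e] = sse_epoch / (double)n;
    if (!std::isfinite(history[e]))
      stop("training loss is not finite; lower the learning rate or check input scaling");
  }
  return List::create(_["weights"] = weights_to_list(w, weights),
                      _["history"] = history);
}
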