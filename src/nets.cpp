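// Minimal neural-network engine for amortized parameter estimation and goal
// classification: an optional gated-recurrent-unit (GRU) front end over
// 5-channel sequences, a swish-activated fully connected head with inverted
// dropout after the first hidden layer, MSE or softmax-cross-entropy loss,
// and Adam with global-norm gradient clipping.  Training order, weight
// initialization and dropout masks all use R's RNG, so runs are reproducible
// under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline arma::mat sigm(const arma::mat &x) { return 1.0 / (1.0 + arma::exp(-x)); }
inline arma::mat swish(const arma::mat &x) { return x % sigm(x); }
inline arma::mat swish_deriv(const arma::mat &x) {
  arma::mat s = sigm(x);
  return s % (1.0 + x % (1.0 - s));
}

struct NetSpec {
  bool recurrent;
  int n_input;   // channels per timestep (recurrent) or feature count
  int gru_width; // hidden state size H (recurrent only)
  std::vector<int> hidden;
  int n_output;
  bool softmax;  // classification head; otherwise linear + MSE
  double p_drop;
};

NetSpec read_spec(const List &net) {
  NetSpec sp;
  sp.recurrent = as<bool>(net["recurrent"]);
  sp.n_input = as<int>(net["n_input"]);
  sp.gru_width = as<int>(net["gru_width"]);
  sp.hidden = as<std::vector<int>>(net["hidden"]);
  sp.n_output = as<int>(net["n_output"]);
  sp.softmax = as<std::string>(net["loss"]) == "softmax";
  sp.p_drop = as<double>(net["p_drop"]);
  return sp;
}

std::vector<arma::mat> read_weights(const List &net) {
  List w = net["weights"];
  std::vector<arma::mat> out;
  out.reserve(w.size());
  for (int i = 0; i < w.size(); i++) out.push_back(as<arma::mat>(w[i]));
  return out;
}

List wrap_weights(const std::vector<arma::mat> &w, const CharacterVector &nm) {
  List out(w.size());
  for (size_t i = 0; i < w.size(); i++) out[i] = wrap(w[i]);
  out.attr("names") = nm;
  return out;
}

inline arma::mat glorot(int nout, int nin) {
  const double lim = std::sqrt(6.0 / (nin + nout));
  arma::mat m(nout, nin);
  for (arma::uword i = 0; i < m.n_elem; i++)
    m[i] = lim * (2.0 * unif_rand() - 1.0);
  return m;
}

// Weight layout: [Wz, Wr, Wn, Uz, Ur, Un, bz, br, bn] when recurrent, then
// for each hidden layer W_k (out x in), b_k (1 x out), and finally Wout, bout.
const int GRU_NW = 9;

// Forward pass through the head given its input (B x F_head).  Stores
// pre-activations and post-dropout activations when caches are supplied.
arma::mat head_forward(const NetSpec &sp, const std::vector<arma::mat> &w,
                       int off, const arma::mat &input, bool use_dropout,
                       std::vector<arma::mat> *pre, std::vector<arma::mat> *act,
                       std::vector<arma::mat> *masks) {
  arma::mat cur = input;
  const int nh = sp.hidden.size();
  for (int k = 0; k < nh; k++) {
    arma::mat A = cur * w[off + 2 * k].t();
    A.each_row() += w[off + 2 * k + 1].row(0);
    arma::mat a = swish(A);
    if (k == 0 && use_dropout && sp.p_drop > 0) {
      arma::mat mask(a.n_rows, a.n_cols);
      const double keep = 1.0 - sp.p_drop;
      for (arma::uword i = 0; i < mask.n_elem; i++)
        mask[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      a %= mask;
      if (masks) masks->push_back(mask);
    }
    if (pre) pre->push_back(A);
    if (act) act->push_back(a);
    cur = a;
  }
  arma::mat out = cur * w[off + 2 * nh].t();
  out.each_row() += w[off + 2 * nh + 1].row(0);
  if (sp.softmax) {
    out.each_col() -= arma::max(out, 1);
    out = arma::exp(out);
    out.each_col() /= arma::sum(out, 1);
  }
  return out;
}

struct GruCache {
  arma::cube Z, R, N, H; // each B x H x T
};

// GRU forward over a batch cube (B x F x T); returns final hidden state.
arma::mat gru_forward(const NetSpec &sp, const std::vector<arma::mat> &w,
                      const arma::cube &X, GruCache *cache) {
  const int B = X.n_rows, T = X.n_slices, H = sp.gru_width;
  arma::mat Hprev(B, H, arma::fill::zeros);
  if (cache) {
    cache->Z.set_size(B, H, T);
    cache->R.set_size(B, H, T);
    cache->N.set_size(B, H, T);
    cache->H.set_size(B, H, T);
  }
  for (int t = 0; t < T; t++) {
    const arma::mat &Xt = X.slice(t);
    arma::mat Az = Xt * w[0].t() + Hprev * w[3].t();
    Az.each_row() += w[6].row(0);
    arma::mat Ar = Xt * w[1].t() + Hprev * w[4].t();
    Ar.each_row() += w[7].row(0);
    arma::mat Z = sigm(Az), R = sigm(Ar);
    arma::mat An = Xt * w[2].t() + (R % Hprev) * w[5].t();
    An.each_row() += w[8].row(0);
    arma::mat N = arma::tanh(An);
    arma::mat Hcur = (1.0 - Z) % N + Z % Hprev;
    if (cache) {
      cache->Z.slice(t) = Z;
      cache->R.slice(t) = R;
      cache->N.slice(t) = N;
      cache->H.slice(t) = Hcur;
    }
    Hprev = Hcur;
  }
  return Hprev;
}

// Backpropagation through time; accumulates GRU weight gradients into g and
// returns nothing (input gradients are not needed).
void gru_backward(const NetSpec &sp, const std::vector<arma::mat> &w,
                  const arma::cube &X, const GruCache &c, arma::mat dH,
                  std::vector<arma::mat> &g) {
  const int B = X.n_rows, T = X.n_slices, H = sp.gru_width;
  for (int t = T - 1; t >= 0; t--) {
    const arma::mat &Xt = X.slice(t);
    arma::mat Hprev = (t == 0) ? arma::mat(B, H, arma::fill::zeros)
                               : arma::mat(c.H.slice(t - 1));
    const arma::mat &Z = c.Z.slice(t);
    const arma::mat &R = c.R.slice(t);
    const arma::mat &N = c.N.slice(t);
    arma::mat dZ = dH % (Hprev - N);
    arma::mat dN = dH % (1.0 - Z);
    arma::mat dHprev = dH % Z;
    arma::mat dAn = dN % (1.0 - N % N);
    g[2] += dAn.t() * Xt;
    g[5] += dAn.t() * (R % Hprev);
    g[8].row(0) += arma::sum(dAn, 0);
    arma::mat dRH = dAn * w[5];
    arma::mat dR = dRH % Hprev;
    dHprev += dRH % R;
    arma::mat dAz = dZ % Z % (1.0 - Z);
    arma::mat dAr = dR % R % (1.0 - R);
    g[0] += dAz.t() * Xt;
    g[3] += dAz.t() * Hprev;
    g[6].row(0) += arma::sum(dAz, 0);
    g[1] += dAr.t() * Xt;
    g[4] += dAr.t() * Hprev;
    g[7].row(0) += arma::sum(dAr, 0);
    dHprev += dAz * w[3] + dAr * w[4];
    dH = dHprev;
  }
}

// Full forward + backward on one batch.  Returns loss; fills gradient vector
// g (same layout as weights).  Y is B x K (one-hot for softmax).
double net_grad_core(const NetSpec &sp, const std::vector<arma::mat> &w,
                     const arma::cube &Xseq, const arma::mat &Xflat,
                     const arma::mat &Y, bool use_dropout,
                     std::vector<arma::mat> &g, double *acc_out) {
  const int off = sp.recurrent ? GRU_NW : 0;
  const int nh = sp.hidden.size();
  GruCache cache;
  arma::mat head_in = sp.recurrent ? gru_forward(sp, w, Xseq, &cache) : Xflat;
  std::vector<arma::mat> pre, act, masks;
  arma::mat out =
      head_forward(sp, w, off, head_in, use_dropout, &pre, &act, &masks);
  const int B = out.n_rows, K = out.n_cols;
  double loss;
  arma::mat dOut(B, K);
  if (sp.softmax) {
    arma::mat p = arma::clamp(out, 1e-12, 1.0);
    loss = -arma::accu(Y % arma::log(p)) / B;
    dOut = (out - Y) / B;
  } else {
    arma::mat e = out - Y;
    loss = arma::accu(e % e) / (B * K);
    dOut = 2.0 * e / (B * K);
  }
  if (acc_out) {
    arma::ucolvec ph = arma::index_max(out, 1), th = arma::index_max(Y, 1);
    *acc_out = arma::mean(arma::conv_to<arma::vec>::from(ph == th));
  }
  // head backward
  arma::mat d = dOut;
  g[off + 2 * nh] += d.t() * (nh > 0 ? act[nh - 1] : head_in);
  g[off + 2 * nh + 1].row(0) += arma::sum(d, 0);
  d = d * w[off + 2 * nh];
  for (int k = nh - 1; k >= 0; k--) {
    if (k == 0 && use_dropout && sp.p_drop > 0) d %= masks[0];
    arma::mat dA = d % swish_deriv(pre[k]);
    g[off + 2 * k] += dA.t() * (k > 0 ? act[k - 1] : head_in);
    g[off + 2 * k + 1].row(0) += arma::sum(dA, 0);
    d = dA * w[off + 2 * k];
  }
  if (sp.recurrent) gru_backward(sp, w, Xseq, cache, d, g);
  return loss;
}

std::vector<arma::mat> zero_like(const std::vector<arma::mat> &w) {
  std::vector<arma::mat> g;
  g.reserve(w.size());
  for (const auto &m : w) g.emplace_back(arma::size(m), arma::fill::zeros);
  return g;
}

arma::cube gather_cube(const arma::cube &X, const arma::uvec &idx) {
  arma::cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (arma::uword t = 0; t < X.n_slices; t++)
    out.slice(t) = X.slice(t).rows(idx);
  return out;
}

// Batched forward pass for evaluation/prediction (no gradient).
arma::mat net_forward_all(const NetSpec &sp, const std::vector<arma::mat> &w,
                          const arma::cube &Xseq, const arma::mat &Xflat,
                          bool use_dropout, int chunk = 512) {
  const int off = sp.recurrent ? GRU_NW : 0;
  const int n = sp.recurrent ? Xseq.n_rows : Xflat.n_rows;
  arma::mat out(n, sp.n_output);
  for (int lo = 0; lo < n; lo += chunk) {
    const int hi = std::min(lo + chunk, n) - 1;
    arma::uvec idx = arma::regspace<arma::uvec>(lo, hi);
    arma::mat head_in;
    if (sp.recurrent) {
      arma::cube Xb = gather_cube(Xseq, idx);
      head_in = gru_forward(sp, w, Xb, nullptr);
    } else {
      head_in = Xflat.rows(idx);
    }
    out.rows(idx) = head_forward(sp, w, off, head_in, use_dropout, nullptr,
                                 nullptr, nullptr);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_net_init(bool recurrent, int n_input, int gru_width,
                  IntegerVector hidden, int n_output, std::string loss,
                  double p_drop) {
  RNGScope scope;
  std::vector<arma::mat> w;
  std::vector<std::string> nm;
  if (recurrent) {
    const char *gn[] = {"Wz", "Wr", "Wn", "Uz", "Ur", "Un", "bz", "br", "bn"};
    for (int k = 0; k < 3; k++) { w.push_back(glorot(gru_width, n_input)); nm.push_back(gn[k]); }
    for (int k = 0; k < 3; k++) { w.push_back(glorot(gru_width, gru_width)); nm.push_back(gn[3 + k]); }
    for (int k = 0; k < 3; k++) { w.push_back(arma::mat(1, gru_width, arma::fill::zeros)); nm.push_back(gn[6 + k]); }
    // bias the update ("keep") gate positive so the hidden state starts with
    // a multi-step memory timescale and gradients reach early timesteps
    w[6].fill(1.0);
  }
  int fan = recurrent ? gru_width : n_input;
  for (int k = 0; k < hidden.size(); k++) {
    w.push_back(glorot(hidden[k], fan));
    nm.push_back("W" + std::to_string(k + 1));
    w.push_back(arma::mat(1, hidden[k], arma::fill::zeros));
    nm.push_back("b" + std::to_string(k + 1));
    fan = hidden[k];
  }
  w.push_back(glorot(n_output, fan));
  nm.push_back("Wout");
  w.push_back(arma::mat(1, n_output, arma::fill::zeros));
  nm.push_back("bout");
  return List::create(
      _["recurrent"] = recurrent, _["n_input"] = n_input,
      _["gru_width"] = gru_width, _["hidden"] = hidden,
      _["n_output"] = n_output, _["loss"] = loss, _["p_drop"] = p_drop,
      _["weights"] = wrap_weights(w, CharacterVector(nm.begin(), nm.end())));
}

// Train with Adam.  X: cube (n x F x T) when recurrent else matrix (n x F).
// train_idx/val_idx are 1-based.  In iteration mode `n_steps` counts
// minibatch updates and validation runs every `val_every` steps; in epoch
// mode `n_steps` counts epochs with validation after each.
// [[Rcpp::export]]
List cpp_net_train(List net, SEXP X, arma::mat Y, arma::uvec train_idx,
                   arma::uvec val_idx, int n_steps, bool iter_mode, int batch,
                   double lr, double clipnorm, int val_every) {
  NetSpec sp = read_spec(net);
  std::vector<arma::mat> w = read_weights(net);
  arma::cube Xseq;
  arma::mat Xflat;
  if (sp.recurrent) Xseq = as<arma::cube>(X); else Xflat = as<arma::mat>(X);
  train_idx -= 1;
  val_idx -= 1;
  const int n_train = train_idx.n_elem;
  if (n_train < 1) stop("empty training set");
  const int steps_per_epoch = (n_train + batch - 1) / batch;
  const int total_steps = iter_mode ? n_steps : n_steps * steps_per_epoch;
  if (val_every <= 0) val_every = iter_mode ? 100 : steps_per_epoch;

  std::vector<arma::mat> m = zero_like(w), v = zero_like(w);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double b1t = 1.0, b2t = 1.0;
  std::vector<double> tr_loss(total_steps), tr_acc;
  if (sp.softmax) tr_acc.resize(total_steps);
  std::vector<double> va_step, va_loss, va_acc;
  arma::uvec order = train_idx;
  RNGScope scope;

  auto validate = [&](int step) {
    if (val_idx.n_elem == 0) return;
    arma::mat out;
    if (sp.recurrent) {
      arma::cube Xv = gather_cube(Xseq, val_idx);
      out = net_forward_all(sp, w, Xv, arma::mat(), false);
    } else {
      arma::mat Xv = Xflat.rows(val_idx);
      out = net_forward_all(sp, w, arma::cube(), Xv, false);
    }
    arma::mat Yv = Y.rows(val_idx);
    double loss;
    if (sp.softmax) {
      arma::mat p = arma::clamp(out, 1e-12, 1.0);
      loss = -arma::accu(Yv % arma::log(p)) / Yv.n_rows;
      arma::ucolvec ph = arma::index_max(out, 1), th = arma::index_max(Yv, 1);
      va_acc.push_back(arma::mean(arma::conv_to<arma::vec>::from(ph == th)));
    } else {
      arma::mat e = out - Yv;
      loss = arma::accu(e % e) / e.n_elem;
    }
    va_step.push_back(step + 1);
    va_loss.push_back(loss);
  };

  for (int step = 0; step < total_steps; step++) {
    const int pos = step % steps_per_epoch;
    if (pos == 0) { // Fisher-Yates reshuffle each epoch via R's RNG
      for (int i = n_train - 1; i > 0; i--) {
        int j = static_cast<int>(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
    }
    const int lo = pos * batch;
    const int hi = std::min(lo + batch, n_train) - 1;
    arma::uvec idx = order.subvec(lo, hi);
    arma::mat Yb = Y.rows(idx);
    std::vector<arma::mat> g = zero_like(w);
    double acc = 0.0, loss;
    if (sp.recurrent) {
      arma::cube Xb = gather_cube(Xseq, idx);
      loss = net_grad_core(sp, w, Xb, arma::mat(), Yb, true, g,
                           sp.softmax ? &acc : nullptr);
    } else {
      arma::mat Xb = Xflat.rows(idx);
      loss = net_grad_core(sp, w, arma::cube(), Xb, Yb, true, g,
                           sp.softmax ? &acc : nullptr);
    }
    tr_loss[step] = loss;
    if (sp.softmax) tr_acc[step] = acc;
    // global-norm clip
    if (clipnorm > 0) {
      double sq = 0.0;
      for (const auto &gm : g) sq += arma::accu(gm % gm);
      const double nrm = std::sqrt(sq);
      if (nrm > clipnorm)
        for (auto &gm : g) gm *= clipnorm / nrm;
    }
    b1t *= b1;
    b2t *= b2;
    for (size_t k = 0; k < w.size(); k++) {
      m[k] = b1 * m[k] + (1.0 - b1) * g[k];
      v[k] = b2 * v[k] + (1.0 - b2) * (g[k] % g[k]);
      w[k] -= lr * (m[k] / (1.0 - b1t)) /
              (arma::sqrt(v[k] / (1.0 - b2t)) + eps);
    }
    if ((step + 1) % val_every == 0 || step == total_steps - 1) validate(step);
    if ((step + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = clone(net);
  out["weights"] = wrap_weights(w, as<List>(net["weights"]).attr("names"));
  List hist = List::create(
      _["step"] = arma::regspace<arma::vec>(1, total_steps),
      _["train_loss"] = NumericVector(tr_loss.begin(), tr_loss.end()),
      _["val_step"] = NumericVector(va_step.begin(), va_step.end()),
      _["val_loss"] = NumericVector(va_loss.begin(), va_loss.end()));
  if (sp.softmax) {
    hist["train_acc"] = NumericVector(tr_acc.begin(), tr_acc.end());
    hist["val_acc"] = NumericVector(va_acc.begin(), va_acc.end());
  }
  return List::create(_["net"] = out, _["history"] = hist);
}

// [[Rcpp::export]]
arma::mat cpp_net_predict(List net, SEXP X, bool mc_dropout) {
  NetSpec sp = read_spec(net);
  std::vector<arma::mat> w = read_weights(net);
  RNGScope scope;
  if (sp.recurrent)
    return net_forward_all(sp, w, as<arma::cube>(X), arma::mat(), mc_dropout);
  return net_forward_all(sp, w, arma::cube(), as<arma::mat>(X), mc_dropout);
}

// Loss and analytic gradients without dropout; used to verify the
// backpropagation against finite differences in the test suite.
// [[Rcpp::export]]
List cpp_net_grad(List net, SEXP X, arma::mat Y) {
  NetSpec sp = read_spec(net);
  sp.p_drop = 0.0;
  std::vector<arma::mat> w = read_weights(net);
  std::vector<arma::mat> g = zero_like(w);
  double loss;
  if (sp.recurrent)
    loss = net_grad_core(sp, w, as<arma::cube>(X), arma::mat(), Y, false, g,
                         nullptr);
  else
    loss = net_grad_core(sp, w, arma::cube(), as<arma::mat>(X), Y, false, g,
                         nullptr);
  return List::create(
      _["loss"] = loss,
      _["grad"] = wrap_weights(g, as<List>(net["weights"]).attr("names")));
}
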