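// Single-layer LSTM sequence classifier with a dense + sigmoid output
// head, trained by backpropagation through time with Adam on a
// multi-label-style binary cross-entropy over the 10 class outputs
// (decoded by argmax). All randomness (weight init, batch shuffling)
// is supplied from R so training is deterministic given the R seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmWeights {
  mat Wx, Wh, Wy;   // D x 4H, H x 4H, H x C
  rowvec b, by;     // 4H, C

  static LstmWeights from_list(const Rcpp::List& w) {
    LstmWeights out;
    out.Wx = Rcpp::as<mat>(w["Wx"]);
    out.Wh = Rcpp::as<mat>(w["Wh"]);
    out.Wy = Rcpp::as<mat>(w["Wy"]);
    out.b = Rcpp::as<rowvec>(w["b"]);
    out.by = Rcpp::as<rowvec>(w["by"]);
    return out;
  }

  Rcpp::List to_list() const {
    return Rcpp::List::create(Rcpp::Named("Wx") = Wx,
                              Rcpp::Named("Wh") = Wh,
                              Rcpp::Named("Wy") = Wy,
                              Rcpp::Named("b") = b,
                              Rcpp::Named("by") = by);
  }
};

// Forward pass over a batch; X is cube (N x D x T) restricted to `rows`.
// Gate layout along the 4H axis: [input, forget, candidate, output].
struct ForwardCache {
  cube I, Fg, G, O, C, Ctanh, H;  // each B x Hd x T
  mat scores;                     // B x C (sigmoid outputs)
};

// pool_mean: readout from the time-mean of hidden states instead of the
// last state (robust when informative frames sit mid-sequence).
ForwardCache lstm_forward(const cube& X, const uvec& rows,
                          const LstmWeights& w, bool keep_cache,
                          bool pool_mean) {
  const uword B = rows.n_elem, T = X.n_slices, Hd = w.Wh.n_rows;
  ForwardCache fc;
  if (keep_cache) {
    fc.I.set_size(B, Hd, T); fc.Fg.set_size(B, Hd, T);
    fc.G.set_size(B, Hd, T); fc.O.set_size(B, Hd, T);
    fc.C.set_size(B, Hd, T); fc.Ctanh.set_size(B, Hd, T);
    fc.H.set_size(B, Hd, T);
  }
  mat h(B, Hd, fill::zeros), c(B, Hd, fill::zeros);
  mat hsum(B, Hd, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat xt = X.slice(t).rows(rows);
    mat z = xt * w.Wx + h * w.Wh;
    z.each_row() += w.b;
    mat i = sigmoid(z.cols(0, Hd - 1));
    mat f = sigmoid(z.cols(Hd, 2 * Hd - 1));
    mat g = tanh(z.cols(2 * Hd, 3 * Hd - 1));
    mat o = sigmoid(z.cols(3 * Hd, 4 * Hd - 1));
    c = f % c + i % g;
    mat ct = tanh(c);
    h = o % ct;
    if (pool_mean) hsum += h;
    if (keep_cache) {
      fc.I.slice(t) = i; fc.Fg.slice(t) = f; fc.G.slice(t) = g;
      fc.O.slice(t) = o; fc.C.slice(t) = c; fc.Ctanh.slice(t) = ct;
      fc.H.slice(t) = h;
    }
  }
  mat hread = pool_mean ? mat(hsum / (double)T) : h;
  mat logits = hread * w.Wy;
  logits.each_row() += w.by;
  fc.scores = sigmoid(logits);
  return fc;
}

struct Grads {
  mat Wx, Wh, Wy;
  rowvec b, by;
  void zeros_like(const LstmWeights& w) {
    Wx.zeros(size(w.Wx)); Wh.zeros(size(w.Wh)); Wy.zeros(size(w.Wy));
    b.zeros(w.b.n_elem); by.zeros(w.by.n_elem);
  }
};

// Backward pass; Y is the B x C one-hot target block.
double lstm_backward(const cube& X, const uvec& rows, const mat& Y,
                     const LstmWeights& w, const ForwardCache& fc,
                     Grads& g, bool pool_mean) {
  const uword B = rows.n_elem, T = X.n_slices, Hd = w.Wh.n_rows;
  g.zeros_like(w);
  const mat& p = fc.scores;
  // binary cross-entropy summed over classes, averaged over the batch
  double loss = -accu(Y % log(p + 1e-12) +
                      (1.0 - Y) % log(1.0 - p + 1e-12)) / B;
  mat dlogits = (p - Y) / B;   // d(BCE)/dlogit through the sigmoid
  mat hread(B, Hd, fill::zeros);
  if (pool_mean) {
    for (uword t = 0; t < T; ++t) hread += fc.H.slice(t);
    hread /= (double)T;
  } else {
    hread = fc.H.slice(T - 1);
  }
  g.Wy = hread.t() * dlogits;
  g.by = sum(dlogits, 0);
  mat dhout = dlogits * w.Wy.t();
  mat dh = pool_mean ? mat(dhout / (double)T) : dhout;
  mat dc(B, Hd, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& i = fc.I.slice(t);
    const mat& f = fc.Fg.slice(t);
    const mat& gg = fc.G.slice(t);
    const mat& o = fc.O.slice(t);
    const mat& ct = fc.Ctanh.slice(t);
    mat dct = dc + dh % o % (1.0 - ct % ct);
    mat cprev = (t == 0) ? mat(B, Hd, fill::zeros) : fc.C.slice(t - 1);
    mat dzi = (dct % gg) % i % (1.0 - i);
    mat dzf = (dct % cprev) % f % (1.0 - f);
    mat dzg = (dct % i) % (1.0 - gg % gg);
    mat dzo = (dh % ct) % o % (1.0 - o);
    mat dZ = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));
    mat xt = X.slice(t).rows(rows);
    g.Wx += xt.t() * dZ;
    if (t > 0) {
      g.Wh += fc.H.slice(t - 1).t() * dZ;
    }
    g.b += sum(dZ, 0);
    dh = dZ * w.Wh.t();
    if (pool_mean) dh += dhout / (double)T;
    dc = dct % f;
  }
  return loss;
}

void clip_global_norm(Grads& g, double max_norm) {
  double sq = accu(square(g.Wx)) + accu(square(g.Wh)) +
              accu(square(g.Wy)) + accu(square(g.b)) +
              accu(square(g.by));
  double nrm = std::sqrt(sq);
  if (nrm > max_norm) {
    double s = max_norm / nrm;
    g.Wx *= s; g.Wh *= s; g.Wy *= s; g.b *= s; g.by *= s;
  }
}

struct AdamState {
  Grads m, v;
  long step = 0;
  void init(const LstmWeights& w) { m.zeros_like(w); v.zeros_like(w); }
};

template <typename M>
void adam_update_one(M& w, M& m, M& v, const M& g, double lr,
                     double b1, double b2, double eps,
                     double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

void adam_update(LstmWeights& w, AdamState& st, const Grads& g,
                 double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.step += 1;
  double bc1 = 1.0 - std::pow(b1, (double)st.step);
  double bc2 = 1.0 - std::pow(b2, (double)st.step);
  adam_update_one(w.Wx, st.m.Wx, st.v.Wx, g.Wx, lr, b1, b2, eps, bc1, bc2);
  adam_update_one(w.Wh, st.m.Wh, st.v.Wh, g.Wh, lr, b1, b2, eps, bc1, bc2);
  adam_update_one(w.Wy, st.m.Wy, st.v.Wy, g.Wy, lr, b1, b2, eps, bc1, bc2);
  adam_update_one(w.b, st.m.b, st.v.b, g.b, lr, b1, b2, eps, bc1, bc2);
  adam_update_one(w.by, st.m.by, st.v.by, g.by, lr, b1, b2, eps, bc1, bc2);
}

}  // namespace

// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(const arma::cube& X, const arma::uvec& y,
                          int n_class, Rcpp::List init_weights,
                          const arma::umat& epoch_order,
                          int batch_size, double lr, double clip_norm,
                          bool pool_mean) {
  const uword N = X.n_rows;
  LstmWeights w = LstmWeights::from_list(init_weights);
  mat Yfull(N, n_class, fill::zeros);
  for (uword i = 0; i < N; ++i) Yfull(i, y(i)) = 1.0;

  AdamState st;
  st.init(w);
  Grads g;
  const uword epochs = epoch_order.n_rows;
  vec loss_hist(epochs, fill::zeros);
  for (uword e = 0; e < epochs; ++e) {
    double eloss = 0.0;
    uword nb = 0;
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N) - 1;
      uvec rows = epoch_order.row(e).cols(start, stop).t();
      ForwardCache fc = lstm_forward(X, rows, w, true, pool_mean);
      double l = lstm_backward(X, rows, Yfull.rows(rows), w, fc, g,
                               pool_mean);
      clip_global_norm(g, clip_norm);
      adam_update(w, st, g, lr);
      eloss += l;
      ++nb;
    }
    loss_hist(e) = eloss / nb;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = w.to_list(),
                            Rcpp::Named("loss") = loss_hist);
}

// [[Rcpp::export(name = ".lstm_scores_cpp")]]
arma::mat lstm_scores_cpp(const arma::cube& X, Rcpp::List weights,
                          bool pool_mean) {
  LstmWeights w = LstmWeights::from_list(weights);
  uvec rows = regspace<uvec>(0, X.n_rows - 1);
  ForwardCache fc = lstm_forward(X, rows, w, false, pool_mean);
  return fc.scores;
}

// [[Rcpp::export(name = ".lstm_loss_grad_cpp")]]
Rcpp::List lstm_loss_grad_cpp(const arma::cube& X, const arma::uvec& y,
                              int n_class, Rcpp::List weights,
                              bool pool_mean) {
  LstmWeights w = LstmWeights::from_list(weights);
  const uword N = X.n_rows;
  mat Y(N, n_class, fill::zeros);
  for (uword i = 0; i < N; ++i) Y(i, y(i)) = 1.0;
  uvec rows = regspace<uvec>(0, N - 1);
  ForwardCache fc = lstm_forward(X, rows, w, true, pool_mean);
  Grads g;
  double loss = lstm_backward(X, rows, Y, w, fc, g, pool_mean);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grad") = Rcpp::List::create(
          Rcpp::Named("Wx") = g.Wx, Rcpp::Named("Wh") = g.Wh,
          Rcpp::Named("Wy") = g.Wy, Rcpp::Named("b") = g.b,
          Rcpp::Named("by") = g.by));
}
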