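// Elman-style recurrent vergence forecaster: forward pass and full-batch
// gradient-descent training with backpropagation through time.
//
//   h_t = tanh(Wxh x_t + Whh h_{t-1} + b_h)
//   V_t = logistic(Why h_t + b_y)
//
// x_t is the input feature vector (normalized dialogical time and the
// previous conditioning vergence under teacher forcing), V_t the
// predicted vergence. The logistic output keeps predictions in [0, 1].
// Loss is mean squared error over the sequence. Training is exact
// full-sequence BPTT with plain gradient descent, so a run is
// deterministic given the initial weights.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static void forward_pass(const NumericMatrix& Wxh, const NumericMatrix& Whh,
                         const NumericVector& bh, const NumericVector& Why,
                         double by, const NumericMatrix& X,
                         const NumericVector& h0,
                         NumericMatrix& Hs, NumericVector& yhat) {
  const int T = X.nrow(), p = X.ncol(), H = bh.size();
  std::vector<double> h(h0.begin(), h0.end()), hnew(H);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < H; ++i) {
      double z = bh[i];
      for (int j = 0; j < p; ++j) z += Wxh(i, j) * X(t, j);
      for (int k = 0; k < H; ++k) z += Whh(i, k) * h[k];
      hnew[i] = std::tanh(z);
    }
    double o = by;
    for (int i = 0; i < H; ++i) {
      Hs(i, t) = hnew[i];
      o += Why[i] * hnew[i];
      h[i] = hnew[i];
    }
    yhat[t] = logistic(o);
  }
}

// [[Rcpp::export]]
List rnn_forward_cpp(NumericMatrix Wxh, NumericMatrix Whh, NumericVector bh,
                     NumericVector Why, double by, NumericMatrix X,
                     NumericVector h0) {
  const int T = X.nrow(), H = bh.size();
  NumericMatrix Hs(H, T);
  NumericVector yhat(T);
  forward_pass(Wxh, Whh, bh, Why, by, X, h0, Hs, yhat);
  return List::create(_["yhat"] = yhat, _["H"] = Hs);
}

// [[Rcpp::export]]
List rnn_train_cpp(NumericMatrix Wxh, NumericMatrix Whh, NumericVector bh,
                   NumericVector Why, double by, NumericMatrix X,
                   NumericVector y, int epochs, double lr) {
  const int T = X.nrow(), p = X.ncol(), H = bh.size();
  NumericMatrix Hs(H, T);
  NumericVector yhat(T);
  NumericVector loss(epochs);
  NumericVector h0(H); // zero initial hidden state
  NumericMatrix dWxh(H, p), dWhh(H, H);
  std::vector<double> dbh(H), dWhy(H), dh(H), dz(H), dh_next(H);
  int diverged_epoch = -1;

  for (int e = 0; e < epochs; ++e) {
    forward_pass(Wxh, Whh, bh, Why, by, X, h0, Hs, yhat);
    double L = 0.0;
    for (int t = 0; t < T; ++t) {
      const double r = yhat[t] - y[t];
      L += r * r;
    }
    L /= T;
    loss[e] = L;
    if (!std::isfinite(L)) { diverged_epoch = e + 1; break; }

    std::fill(dWxh.begin(), dWxh.end(), 0.0);
    std::fill(dWhh.begin(), dWhh.end(), 0.0);
    std::fill(dbh.begin(), dbh.end(), 0.0);
    std::fill(dWhy.begin(), dWhy.end(), 0.0);
    std::fill(dh_next.begin(), dh_next.end(), 0.0);
    double dby = 0.0;

    for (int t = T - 1; t >= 0; --t) {
      const double dyo = 2.0 * (yhat[t] - y[t]) / T *
                         yhat[t] * (1.0 - yhat[t]);
      dby += dyo;
      for (int i = 0; i < H; ++i) {
        dWhy[i] += dyo * Hs(i, t);
        dh[i] = dh_next[i] + Why[i] * dyo;
        dz[i] = dh[i] * (1.0 - Hs(i, t) * Hs(i, t));
        dbh[i] += dz[i];
        for (int j = 0; j < p; ++j) dWxh(i, j) += dz[i] * X(t, j);
      }
      if (t > 0) {
        for (int i = 0; i < H; ++i)
          for (int k = 0; k < H; ++k) dWhh(i, k) += dz[i] * Hs(k, t - 1);
      }
      for (int k = 0; k < H; ++k) {
        double acc = 0.0;
        for (int i = 0; i < H; ++i) acc += Whh(i, k) * dz[i];
        dh_next[k] = acc;
      }
    }

    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < p; ++j) Wxh(i, j) -= lr * dWxh(i, j);
      for (int k = 0; k < H; ++k) Whh(i, k) -= lr * dWhh(i, k);
      bh[i] -= lr * dbh[i];
      Why[i] -= lr * dWhy[i];
    }
    by -= lr * dby;
  }

  forward_pass(Wxh, Whh, bh, Why, by, X, h0, Hs, yhat);
  return List::create(_["Wxh"] = Wxh, _["Whh"] = Whh, _["bh"] = bh,
                      _["Why"] = Why, _["by"] = by, _["loss"] = loss,
                      _["fitted"] = yhat,
                      _["diverged_epoch"] = diverged_epoch);
}
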