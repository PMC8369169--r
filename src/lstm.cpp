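// A single-direction LSTM layer with exact analytic backward pass.
// Gate layout in the 4H-wide parameter blocks: [input, forget, cell, output].
// The R side composes two of these into a BiLSTM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// X: L x d_in, W: d_in x 4H, U: H x 4H, b: 4H
// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::mat& X, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b) {
  const int L = X.n_rows;
  const int H = U.n_rows;
  mat Hs(L, H), Cs(L, H), G(L, 4 * H);
  rowvec h_prev(H, fill::zeros), c_prev(H, fill::zeros);
  for (int t = 0; t < L; ++t) {
    rowvec z = X.row(t) * W + h_prev * U + b.t();
    for (int k = 0; k < H; ++k) {
      double i = sigm(z[k]);
      double f = sigm(z[H + k]);
      double g = std::tanh(z[2 * H + k]);
      double o = sigm(z[3 * H + k]);
      double c = f * c_prev[k] + i * g;
      G(t, k) = i; G(t, H + k) = f; G(t, 2 * H + k) = g; G(t, 3 * H + k) = o;
      Cs(t, k) = c;
      Hs(t, k) = o * std::tanh(c);
    }
    h_prev = Hs.row(t);
    c_prev = Cs.row(t);
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
                            Rcpp::Named("G") = G);
}

// dH: upstream gradient w.r.t. the hidden outputs (L x H).
// [[Rcpp::export]]
Rcpp::List cpp_lstm_backward(const arma::mat& X, const arma::mat& W,
                             const arma::mat& U, const arma::vec& b,
                             const arma::mat& Hs, const arma::mat& Cs,
                             const arma::mat& G, const arma::mat& dH) {
  const int L = X.n_rows;
  const int H = U.n_rows;
  mat dX(L, X.n_cols, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat dU(U.n_rows, U.n_cols, fill::zeros);
  vec db(4 * H, fill::zeros);
  rowvec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    rowvec dh = dH.row(t) + dh_next;
    rowvec dz(4 * H);
    rowvec dc(H);
    for (int k = 0; k < H; ++k) {
      double i = G(t, k), f = G(t, H + k), g = G(t, 2 * H + k), o = G(t, 3 * H + k);
      double tc = std::tanh(Cs(t, k));
      double c_prev = (t > 0) ? Cs(t - 1, k) : 0.0;
      double dok = dh[k] * tc;
      dc[k] = dh[k] * o * (1.0 - tc * tc) + dc_next[k];
      double dik = dc[k] * g;
      double dfk = dc[k] * c_prev;
      double dgk = dc[k] * i;
      dz[k]         = dik * i * (1.0 - i);
      dz[H + k]     = dfk * f * (1.0 - f);
      dz[2 * H + k] = dgk * (1.0 - g * g);
      dz[3 * H + k] = dok * o * (1.0 - o);
    }
    dW += X.row(t).t() * dz;
    if (t > 0) dU += Hs.row(t - 1).t() * dz;
    db += dz.t();
    dX.row(t) = dz * W.t();
    dh_next = dz * U.t();
    for (int k = 0; k < H; ++k) dc_next[k] = dc[k] * G(t, H + k);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}
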