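// Bilinear word-character fusion, forward and backward, for the training
// loop. Mirrors the R reference implementation used by fuse_sequence();
// the two are held together by the oracle and finite-difference tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Ec: L x d_c rows of the character embedding table (already gathered);
// Ew: n_words x d_w gathered word embedding rows; spans are 0-based
// half-open [start, end) per word covering the L characters.
// [[Rcpp::export]]
Rcpp::List cpp_bilinear_forward(const arma::mat& Ec, const arma::mat& Ew,
                                const arma::mat& W_char, const arma::mat& W_word,
                                const arma::mat& W_attn, double b_attn,
                                const arma::ivec& starts, const arma::ivec& ends,
                                bool collapse) {
  const int L = Ec.n_rows, dc = W_char.n_cols, dw = W_word.n_cols;
  const int nw = Ew.n_rows;
  mat Rc = Ec * W_char;          // L x dc
  mat Rw = Ew * W_word;          // nw x dw
  mat X(L, dc + dw, fill::zeros);
  vec attn(L);
  for (int k = 0; k < nw; ++k) {
    const int s = starts[k], e = ends[k], l = e - s;
    vec proj = W_attn.t() * Rw.row(k).t();       // dc
    vec sc(l);
    for (int i = 0; i < l; ++i) sc[i] = dot(Rc.row(s + i), proj) + b_attn;
    sc -= sc.max();
    vec w = exp(sc);
    w /= accu(w);
    if (collapse) {
      rowvec acc(dc + dw, fill::zeros);
      for (int i = 0; i < l; ++i) {
        acc.cols(0, dc - 1) += w[i] * Rc.row(s + i);
        acc.cols(dc, dc + dw - 1) += w[i] * Rw.row(k);
      }
      for (int i = 0; i < l; ++i) X.row(s + i) = acc;
    } else {
      for (int i = 0; i < l; ++i) {
        X.row(s + i).cols(0, dc - 1) = w[i] * Rc.row(s + i);
        X.row(s + i).cols(dc, dc + dw - 1) = w[i] * Rw.row(k);
      }
    }
    for (int i = 0; i < l; ++i) attn[s + i] = w[i];
  }
  return Rcpp::List::create(
    Rcpp::Named("X") = X, Rcpp::Named("attention") = attn,
    Rcpp::Named("Rc") = Rc, Rcpp::Named("Rw") = Rw);
}

// Backward for the per-character (non-collapsed) form.
// [[Rcpp::export]]
Rcpp::List cpp_bilinear_backward(const arma::mat& dX, const arma::mat& Ec,
                                 const arma::mat& Ew, const arma::mat& Rc,
                                 const arma::mat& Rw, const arma::mat& W_char,
                                 const arma::mat& W_word, const arma::mat& W_attn,
                                 double b_attn, const arma::ivec& starts,
                                 const arma::ivec& ends) {
  const int dc = W_char.n_cols, dw = W_word.n_cols;
  const int nw = Ew.n_rows;
  mat dRc(Rc.n_rows, dc, fill::zeros);
  mat dW_attn(dw, dc, fill::zeros);
  mat dW_word(dw, dw, fill::zeros);
  mat dEw(nw, dw, fill::zeros);
  double db_attn = 0.0;
  for (int k = 0; k < nw; ++k) {
    const int s = starts[k], e = ends[k], l = e - s;
    vec rw = Rw.row(k).t();
    vec proj = W_attn.t() * rw;                    // dc
    vec sc(l);
    for (int i = 0; i < l; ++i) sc[i] = dot(Rc.row(s + i), proj) + b_attn;
    sc -= sc.max();
    vec w = exp(sc);
    w /= accu(w);
    // de_i = dXc_i . Rc_i + dXw_i . rw ; direct grads
    vec de(l);
    vec drw(dw, fill::zeros);
    for (int i = 0; i < l; ++i) {
      rowvec dxc = dX.row(s + i).cols(0, dc - 1);
      rowvec dxw = dX.row(s + i).cols(dc, dc + dw - 1);
      de[i] = dot(dxc, Rc.row(s + i)) + dot(dxw, rw.t());
      dRc.row(s + i) += w[i] * dxc;
      drw += w[i] * dxw.t();
    }
    // softmax backward
    double wde = dot(w, de);
    vec ds = w % (de - wde);
    // s_i = rw' W_attn Rc_i + b
    vec ctRc_ds(dc, fill::zeros);
    for (int i = 0; i < l; ++i) {
      dRc.row(s + i) += ds[i] * proj.t();
      ctRc_ds += ds[i] * Rc.row(s + i).t();
    }
    drw += W_attn * ctRc_ds;
    dW_attn += rw * ctRc_ds.t();
    db_attn += accu(ds);
    // rw = Ew_k W_word
    dW_word += Ew.row(k).t() * drw.t();
    dEw.row(k) = (W_word * drw).t();
  }
  mat dW_char = Ec.t() * dRc;
  mat dEc = dRc * W_char.t();
  return Rcpp::List::create(
    Rcpp::Named("dEc_rows") = dEc, Rcpp::Named("dW_char") = dW_char,
    Rcpp::Named("dW_word") = dW_word, Rcpp::Named("dW_attn") = dW_attn,
    Rcpp::Named("db_attn") = db_attn, Rcpp::Named("dEw_rows") = dEw);
}
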