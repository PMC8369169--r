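// Linear-chain CRF forward-backward in log space. The transition matrix is
// (T+2)x(T+2); the last two states are virtual START and STOP. Entries into
// START and out of STOP are -Inf; exp() of those is 0, so their gradients
// vanish naturally.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double lse(const vec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(v - m)));
}

// [[Rcpp::export]]
Rcpp::List cpp_crf_nll(const arma::mat& em, const arma::mat& trans,
                       const arma::ivec& tags) {
  // tags are 0-based
  const int L = em.n_rows, T = em.n_cols;
  const int start = T, stop = T + 1;
  if ((int)tags.n_elem != L) Rcpp::stop("tag length does not match emissions");
  for (int t = 0; t < L; ++t)
    if (tags[t] < 0 || tags[t] >= T) Rcpp::stop("tag index out of range");

  mat alpha(L, T), beta(L, T);
  for (int j = 0; j < T; ++j) alpha(0, j) = trans(start, j) + em(0, j);
  for (int t = 1; t < L; ++t)
    for (int j = 0; j < T; ++j) {
      vec v(T);
      for (int i = 0; i < T; ++i) v[i] = alpha(t - 1, i) + trans(i, j);
      alpha(t, j) = lse(v) + em(t, j);
    }
  vec fin(T);
  for (int j = 0; j < T; ++j) fin[j] = alpha(L - 1, j) + trans(j, stop);
  const double logZ = lse(fin);

  for (int j = 0; j < T; ++j) beta(L - 1, j) = trans(j, stop);
  for (int t = L - 2; t >= 0; --t)
    for (int i = 0; i < T; ++i) {
      vec v(T);
      for (int j = 0; j < T; ++j) v[j] = trans(i, j) + em(t + 1, j) + beta(t + 1, j);
      beta(t, i) = lse(v);
    }

  // unary marginals -> emission gradient
  mat d_em(L, T);
  for (int t = 0; t < L; ++t)
    for (int j = 0; j < T; ++j)
      d_em(t, j) = std::exp(alpha(t, j) + beta(t, j) - logZ);
  for (int t = 0; t < L; ++t) d_em(t, tags[t]) -= 1.0;

  // pairwise marginals -> transition gradient
  mat d_tr(T + 2, T + 2, fill::zeros);
  for (int t = 0; t + 1 < L; ++t)
    for (int i = 0; i < T; ++i)
      for (int j = 0; j < T; ++j) {
        double lp = alpha(t, i) + trans(i, j) + em(t + 1, j) + beta(t + 1, j) - logZ;
        d_tr(i, j) += std::exp(lp);
      }
  for (int j = 0; j < T; ++j)
    d_tr(start, j) += std::exp(alpha(0, j) + beta(0, j) - logZ);
  for (int j = 0; j < T; ++j)
    d_tr(j, stop) += std::exp(alpha(L - 1, j) + trans(j, stop) - logZ);
  // subtract the observed path's counts
  d_tr(start, tags[0]) -= 1.0;
  for (int t = 0; t + 1 < L; ++t) d_tr(tags[t], tags[t + 1]) -= 1.0;
  d_tr(tags[L - 1], stop) -= 1.0;

  // observed path score
  double score = trans(start, tags[0]) + trans(tags[L - 1], stop);
  for (int t = 0; t < L; ++t) score += em(t, tags[t]);
  for (int t = 0; t + 1 < L; ++t) score += trans(tags[t], tags[t + 1]);

  return Rcpp::List::create(
    Rcpp::Named("nll") = logZ - score,
    Rcpp::Named("log_partition") = logZ,
    Rcpp::Named("d_emissions") = d_em,
    Rcpp::Named("d_transitions") = d_tr);
}
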