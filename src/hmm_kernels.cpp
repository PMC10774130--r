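// Log-space recursions for the discrete Gaussian-emission HMM.
// All routines are single-threaded and deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double logsumexp_vec(const arma::rowvec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

// Forward pass. emis: T x K matrix of log emission densities, A: K x K row
// stochastic transitions, logb: K initial-state log probabilities.
// [[Rcpp::export]]
List hmm_forward_cpp(const arma::mat& emis, const arma::mat& A,
                     const arma::rowvec& logb) {
  const int T = emis.n_rows, K = emis.n_cols;
  arma::mat alpha(T, K);
  alpha.row(0) = logb + emis.row(0);
  for (int t = 1; t < T; ++t) {
    const arma::rowvec prev = alpha.row(t - 1);
    double m = prev.max();
    arma::rowvec w = arma::exp(prev - m);   // 1 x K
    arma::rowvec s = w * A;                 // 1 x K
    alpha.row(t) = emis.row(t) + m + arma::log(s);
  }
  double ll = logsumexp_vec(alpha.row(T - 1));
  return List::create(_["loglik"] = ll, _["alpha"] = alpha);
}

// [[Rcpp::export]]
arma::mat hmm_backward_cpp(const arma::mat& emis, const arma::mat& A) {
  const int T = emis.n_rows, K = emis.n_cols;
  arma::mat beta(T, K, arma::fill::zeros);
  for (int t = T - 2; t >= 0; --t) {
    arma::rowvec u = emis.row(t + 1) + beta.row(t + 1);
    double m = u.max();
    arma::colvec w = arma::exp(u - m).t();  // K x 1
    arma::colvec s = A * w;                 // K x 1
    beta.row(t) = m + arma::log(s).t();
  }
  return beta;
}

// Posterior state marginals gamma (T x K) and summed transition posteriors
// xi_sum (K x K), plus the log-likelihood. Used both for EM and for the
// analytic gradient of the forward log-likelihood.
// [[Rcpp::export]]
List hmm_posteriors_cpp(const arma::mat& emis, const arma::mat& A,
                        const arma::rowvec& logb) {
  const int T = emis.n_rows, K = emis.n_cols;
  List fwd = hmm_forward_cpp(emis, A, logb);
  double ll = fwd["loglik"];
  arma::mat alpha = fwd["alpha"];
  arma::mat beta = hmm_backward_cpp(emis, A);
  arma::mat gamma = arma::exp(alpha + beta - ll);
  // guard tiny numerical drift
  for (int t = 0; t < T; ++t) {
    double s = arma::accu(gamma.row(t));
    if (s > 0) gamma.row(t) /= s;
  }
  arma::mat logA = arma::log(A);
  arma::mat xi_sum(K, K, arma::fill::zeros);
  for (int t = 0; t + 1 < T; ++t) {
    // M(j,i) = alpha(t,j) + logA(j,i) + emis(t+1,i) + beta(t+1,i) - ll <= ~0
    arma::mat M = arma::repmat(alpha.row(t).t(), 1, K) + logA;
    M.each_row() += emis.row(t + 1) + beta.row(t + 1);
    M -= ll;
    xi_sum += arma::exp(M);
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Viterbi decoding; ties broken toward the lowest state index. Returns a
// 1-based path of length T.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(const arma::mat& emis, const arma::mat& A,
                              const arma::rowvec& logb) {
  const int T = emis.n_rows, K = emis.n_cols;
  arma::mat logA = arma::log(A);
  arma::mat delta(T, K);
  arma::imat back(T, K);
  delta.row(0) = logb + emis.row(0);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < K; ++i) {
      double best = -arma::datum::inf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, i);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, i) = best + emis(t, i);
      back(t, i) = arg;
    }
  }
  IntegerVector path(T);
  double best = -arma::datum::inf;
  int arg = 0;
  for (int i = 0; i < K; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); arg = i; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = back(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
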