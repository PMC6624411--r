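// Scaled forward-backward smoothing and Viterbi decoding for a hidden
// Markov chain with precomputed per-step emission log-densities. The
// scaling (per-step normalization plus per-row max subtraction of logB)
// keeps the recursions underflow-free for sequences up to at least 1e5
// steps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List forward_backward_cpp(const arma::mat& logB, const arma::mat& trans,
                          const arma::vec& initDist) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::mat b(T, K);
  arma::vec m(T);
  for (arma::uword t = 0; t < T; ++t) {
    m(t) = logB.row(t).max();
    if (!std::isfinite(m(t)))
      stop("impossible observation: all states have -Inf emission "
           "log-likelihood at step %d", (int)(t + 1));
    b.row(t) = arma::exp(logB.row(t) - m(t));
  }

  arma::mat alpha(T, K);
  arma::vec c(T);
  double loglik = 0.0;
  alpha.row(0) = initDist.t() % b.row(0);
  c(0) = arma::accu(alpha.row(0));
  if (c(0) <= 0) stop("impossible observation at step 1");
  alpha.row(0) /= c(0);
  loglik += std::log(c(0)) + m(0);
  for (arma::uword t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * trans) % b.row(t);
    c(t) = arma::accu(alpha.row(t));
    if (c(t) <= 0)
      stop("impossible observation at step %d", (int)(t + 1));
    alpha.row(t) /= c(t);
    loglik += std::log(c(t)) + m(t);
  }

  arma::mat beta(T, K, arma::fill::ones);
  arma::mat gamma(T, K);
  gamma.row(T - 1) = alpha.row(T - 1);
  arma::cube xi(K, K, T > 1 ? T - 1 : 0);
  for (arma::uword t = T - 1; t-- > 0;) {
    arma::rowvec w = b.row(t + 1) % beta.row(t + 1);
    beta.row(t) = (trans * w.t()).t() / c(t + 1);
    gamma.row(t) = alpha.row(t) % beta.row(t);
    // exact pairwise smoothed marginal; each slice sums to 1
    xi.slice(t) = (trans % (alpha.row(t).t() * w)) / c(t + 1);
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// [[Rcpp::export]]
IntegerVector viterbi_cpp(const arma::mat& logB, const arma::mat& logTrans,
                          const arma::vec& logInit) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::mat delta(T, K);
  arma::umat psi(T, K, arma::fill::zeros);
  delta.row(0) = logInit.t() + logB.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < K; ++j) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logTrans(i, j);
        if (v > best) { best = v; arg = i; }  // ties -> lowest index
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  arma::uword cur = delta.row(T - 1).index_max();
  // index_max returns the first (lowest-index) maximum on exact ties
  path[T - 1] = cur + 1;
  for (arma::uword t = T - 1; t-- > 0;) {
    cur = psi(t + 1, cur);
    path[t] = cur + 1;
  }
  return path;
}
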