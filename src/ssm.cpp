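// Forward filter and backward (two-filter ratio) smoother for the switching
// state-space model on the joint (dynamic x position-bin) state space.
// States are ordered dynamic-major: s = d * n_bins + bin. The likelihood is
// shared across dynamics, so it is passed as T x n_bins and tiled here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List ssm_forward(const arma::mat& loglik, const arma::mat& trans,
                 const arma::vec& init) {
  const arma::uword n_time = loglik.n_rows;
  const arma::uword n_bins = loglik.n_cols;
  const arma::uword n_state = init.n_elem;
  if (trans.n_rows != n_state || trans.n_cols != n_state)
    stop("transition matrix does not match the state space");
  if (n_state % n_bins != 0)
    stop("state count is not a multiple of the grid size");
  const arma::uword n_dyn = n_state / n_bins;

  arma::mat causal(n_time, n_state);
  arma::mat predicted(n_time, n_state);
  double log_evidence = 0.0;
  arma::rowvec pred = init.t();

  for (arma::uword k = 0; k < n_time; ++k) {
    predicted.row(k) = pred;
    const double m = loglik.row(k).max();
    arma::rowvec lik = arma::exp(loglik.row(k) - m);
    arma::rowvec q = pred;
    for (arma::uword d = 0; d < n_dyn; ++d)
      q.subvec(d * n_bins, (d + 1) * n_bins - 1) %= lik;
    const double s = arma::accu(q);
    if (!(s > 0.0))
      stop("posterior mass vanished at time bin %d", (int)(k + 1));
    causal.row(k) = q / s;
    log_evidence += std::log(s) + m;
    if (k + 1 < n_time)
      pred = causal.row(k) * trans;
  }
  return List::create(_["causal"] = causal, _["predicted"] = predicted,
                      _["log_evidence"] = log_evidence);
}

// [[Rcpp::export]]
arma::mat ssm_backward(const arma::mat& causal, const arma::mat& predicted,
                       const arma::mat& trans) {
  const arma::uword n_time = causal.n_rows;
  const arma::uword n_state = causal.n_cols;
  arma::mat acausal(n_time, n_state);
  acausal.row(n_time - 1) = causal.row(n_time - 1);
  for (arma::uword k = n_time - 1; k-- > 0;) {
    arma::rowvec ratio = acausal.row(k + 1);
    const arma::rowvec& pr = predicted.row(k + 1);
    for (arma::uword s = 0; s < n_state; ++s)
      ratio(s) = pr(s) > 0.0 ? ratio(s) / pr(s) : 0.0;
    // sum_{s'} trans(s, s') * ratio(s')
    arma::rowvec a = causal.row(k) % (ratio * trans.t());
    const double ssum = arma::accu(a);
    acausal.row(k) = ssum > 0.0 ? arma::rowvec(a / ssum) : causal.row(k);
  }
  return acausal;
}
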