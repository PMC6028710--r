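// Rate-based recurrent reservoir with FORCE (recursive least squares) readout
// training. The per-timestep loop is compiled: an interpreted loop over
// N^2-cost updates would dominate the test suite's runtime.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// threshold-linear tanh rate: r = max(tanh(x), 0), bounded in [0, 1)
static inline arma::vec rate_of(const arma::vec& x) {
  return arma::clamp(arma::tanh(x), 0.0, arma::datum::inf);
}

// One continuous run of the reservoir (Euler integration).
//   tau dx/dt = -x + gG * JGG * r + JGz * z + JGI * I(t)
// When `learn`, the readout weights are updated by RLS every `update_every`
// steps against `target`. Returns final state, readout trace, per-step
// training error, and (optionally) the full rate trajectory.
// [[Rcpp::export]]
List reservoir_run_cpp(const arma::vec& x0, const arma::mat& JGG,
                       const arma::vec& JGz, const arma::mat& JGI,
                       const arma::vec& w0, const arma::mat& P0,
                       const arma::mat& inputs, const arma::vec& target,
                       double dt, double tau, double gG,
                       bool learn, int update_every, bool record) {
  const int T = inputs.n_cols;
  const int N = x0.n_elem;
  arma::vec x = x0, w = w0;
  arma::mat P = P0;
  arma::vec ztrace(T, arma::fill::zeros);
  arma::vec err(learn ? T : 0, arma::fill::zeros);
  arma::mat rates;
  if (record) rates.set_size(N, T);

  const double a = dt / tau;
  arma::vec r = rate_of(x);
  double z = arma::dot(w, r);

  for (int t = 0; t < T; ++t) {
    r = rate_of(x);
    z = arma::dot(w, r);
    if (learn && (t % update_every == 0)) {
      arma::vec Pr = P * r;
      double rPr = arma::dot(r, Pr);
      double c = 1.0 / (1.0 + rPr);
      P -= (Pr * Pr.t()) * c;
      double e = z - target(t);
      w -= e * c * Pr;
      z = arma::dot(w, r);          // feed back the post-update readout
      err(t) = std::fabs(e);
    } else if (learn) {
      err(t) = std::fabs(z - target(t));
    }
    ztrace(t) = z;
    if (record) rates.col(t) = r;
    x += a * (-x + gG * (JGG * r) + JGz * z + JGI * inputs.col(t));
    if (!x.is_finite())
      stop("reservoir state became non-finite at step %d", t + 1);
  }

  List out = List::create(_["x"] = x, _["w"] = w, _["P"] = P,
                          _["z"] = ztrace, _["err"] = err);
  if (record) out["rates"] = rates;
  return out;
}
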