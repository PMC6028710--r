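// Natural-gradient logistic infomax ICA inner loop on whitened data.
// Full-batch: W <- W + lr * (I - tanh(U/2) U'/T) W. The learning rate anneals
// on update-direction reversals and, after a burn-in, geometrically, so the
// iteration terminates even when near-Gaussian residual dimensions wander.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List infomax_core_cpp(const arma::mat& Z, const arma::mat& W0,
                      int max_iter, double tol, double lr,
                      int burn_in, double anneal) {
  const double Tn = static_cast<double>(Z.n_cols);
  const int k = W0.n_rows;
  arma::mat W = W0;
  arma::mat G_prev(k, k, arma::fill::zeros);
  bool have_prev = false;
  double wchange = arma::datum::inf;
  const arma::mat I = arma::eye(k, k);

  for (int it = 1; it <= max_iter; ++it) {
    arma::mat U = W * Z;
    arma::mat G = I - arma::tanh(0.5 * U) * U.t() / Tn;
    if (have_prev && arma::dot(G, G_prev) < 0)
      lr *= 0.9;
    G_prev = G; have_prev = true;
    arma::mat dW = lr * (G * W);
    W += dW;
    wchange = std::sqrt(arma::dot(dW, dW) / arma::dot(W, W));
    if (wchange < tol)
      return List::create(_["W"] = W, _["converged"] = true,
                          _["iter"] = it, _["delta"] = wchange);
    if (it > burn_in) lr *= anneal;
  }
  return List::create(_["W"] = W, _["converged"] = false,
                      _["iter"] = max_iter, _["delta"] = wchange);
}
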