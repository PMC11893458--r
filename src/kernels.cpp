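// Simulation and backpropagation-through-time kernels shared by the RNN
// testbed and the latent circuit fitter. Both systems follow the same
// rectified Euler update
//   y_t = (1 - alpha) * y_{t-1} + alpha * relu(W y_{t-1} + Win u_t + s_t + noise_t)
// so a single pair of kernels serves both, with dimensions m = N (ambient)
// or m = n (latent).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Forward simulation.
//  W     : m x m recurrent weights
//  Win   : m x c input weights
//  U     : c x K x T input cube (slice t = inputs at step t for all trials)
//  alpha : dt / tau
//  sigma : recurrent noise magnitude (noise sd inside the rectifier is
//          sqrt(2/alpha) * sigma per unit and step); 0 disables noise
//  y0    : m x K initial state
//  Ext   : optional m x K x T cube of extra current injected inside the
//          rectifier (empty cube = none)
// Noise is drawn from R's RNG stream so results are reproducible with
// set.seed() on the R side.
// Returns Y (m x K x (T+1), slice 0 = y0) and the rectifier gate cube
// M (m x K x T, 1 where the preactivation was positive).
// [[Rcpp::export]]
Rcpp::List lc_sim_forward(const arma::mat& W, const arma::mat& Win,
                          const arma::cube& U, double alpha, double sigma,
                          const arma::mat& y0, const arma::cube& Ext) {
  const uword m = W.n_rows, K = U.n_cols, T = U.n_slices;
  const bool has_ext = Ext.n_elem > 0;
  const double nsc = (sigma > 0.0) ? std::sqrt(2.0 / alpha) * sigma : 0.0;

  cube Y(m, K, T + 1), M(m, K, T);
  Y.slice(0) = y0;
  mat a(m, K);
  for (uword t = 0; t < T; ++t) {
    a = W * Y.slice(t) + Win * U.slice(t);
    if (has_ext) a += Ext.slice(t);
    if (nsc > 0.0) {
      // one vectorized draw per step from R's RNG stream (column-major
      // fill, so the stream order matches an element-wise draw)
      Rcpp::NumericVector nv = Rcpp::rnorm(m * K);
      a += nsc * mat(nv.begin(), m, K, false, true);
    }
    M.slice(t) = conv_to<mat>::from(a > 0.0);
    Y.slice(t + 1) = (1.0 - alpha) * Y.slice(t) + alpha * (a % M.slice(t));
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("M") = M);
}

// Backward pass. G is the cube of direct loss gradients dL/dy_t
// (m x K x T, slice t corresponds to Y slice t+1). Returns gradients with
// respect to W and Win. The noise term is additive inside the rectifier and
// therefore only enters through the stored gates M.
// [[Rcpp::export]]
Rcpp::List lc_bptt(const arma::mat& W, const arma::mat& Win,
                   const arma::cube& U, const arma::cube& Y,
                   const arma::cube& M, const arma::cube& G, double alpha) {
  const uword m = W.n_rows, K = U.n_cols, T = U.n_slices;
  mat dW(m, m, fill::zeros), dWin(m, Win.n_cols, fill::zeros);
  mat carry(m, K, fill::zeros), g(m, K), h(m, K);
  for (uword t = T; t-- > 0;) {
    g = G.slice(t) + carry;
    h = alpha * (g % M.slice(t));
    dW += h * Y.slice(t).t();
    dWin += h * U.slice(t).t();
    carry = (1.0 - alpha) * g + W.t() * h;
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("dWin") = dWin);
}
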