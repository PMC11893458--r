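// Full minibatch-Adam optimization loops for RNN task training and latent
// circuit fitting. These mirror the R reference step functions
// (rnn_loss_grad / latent_loss_grad + adam_step) but keep the whole epoch
// loop in compiled code. All randomness (minibatch order, recurrent noise)
// is drawn from R's RNG stream, so runs are reproducible with set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Adam {
  mat m, v;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
};

inline void adam_update(mat& theta, const mat& g_raw, Adam& st, double lr,
                        double wd, long t) {
  mat g = g_raw;
  if (wd > 0) g += wd * theta;
  st.m = 0.9 * st.m + 0.1 * g;
  st.v = 0.999 * st.v + 0.001 * (g % g);
  const double bc1 = 1.0 - std::pow(0.9, (double)t);
  const double bc2 = 1.0 - std::pow(0.999, (double)t);
  theta -= lr * (st.m / bc1) / (sqrt(st.v / bc2) + 1e-8);
}

// rectified Euler forward pass for one minibatch; fills X (m x K x T+1)
// and gates M (m x K x T); draws noise from R's RNG
inline void sim_forward(const mat& W, const mat& Win, const cube& U,
                        double alpha, double nsc, cube& X, cube& M) {
  const uword m = W.n_rows, K = U.n_cols, T = U.n_slices;
  X.slice(0).zeros();
  mat a(m, K);
  for (uword t = 0; t < T; ++t) {
    a = W * X.slice(t) + Win * U.slice(t);
    if (nsc > 0) {
      Rcpp::NumericVector nv = Rcpp::rnorm(m * K);
      a += nsc * mat(nv.begin(), m, K, false, true);
    }
    M.slice(t) = conv_to<mat>::from(a > 0.0);
    X.slice(t + 1) = (1.0 - alpha) * X.slice(t) + alpha * (a % M.slice(t));
  }
}

// backward pass through the recurrence given upstream dL/dx_t in G
inline void bptt(const mat& W, const cube& U, const cube& X, const cube& M,
                 const cube& G, double alpha, mat& dW, mat& dWin) {
  const uword K = U.n_cols, T = U.n_slices;
  dW.zeros(); dWin.zeros();
  mat carry(W.n_rows, K, fill::zeros), g, h;
  for (uword t = T; t-- > 0;) {
    g = G.slice(t) + carry;
    h = alpha * (g % M.slice(t));
    dW += h * X.slice(t).t();
    dWin += h * U.slice(t).t();
    carry = (1.0 - alpha) * g + W.t() * h;
  }
}

// penalty lambda * sum of squared off-diagonal entries of the Gram matrix
// of column-normalized Bio; returns value, adds gradient into dBio
inline double orth_penalty(const mat& Bio, double lambda, mat& dBio) {
  rowvec nrm = sqrt(sum(square(Bio), 0));
  nrm.replace(0.0, 1.0);
  mat Bn = Bio.each_row() / nrm;
  mat Gm = Bn.t() * Bn;
  mat off = Gm - diagmat(Gm);
  mat dBn = 4.0 * lambda * (Bn * off);
  rowvec proj = sum(dBn % Bn, 0);
  mat dtmp = dBn - (Bn.each_row() % proj);
  dBio += dtmp.each_row() / nrm;
  return lambda * accu(square(off));
}

inline mat cayley_Q(const mat& B, uword n) {
  const uword N = B.n_rows;
  mat A = B - B.t();
  mat Mi = solve((eye(N, N) - A).eval(), eye(N, N));
  return (eye(N, N) + A) * Mi.cols(0, n - 1);
}

inline mat cayley_back(const mat& B, const mat& dQ) {
  const uword N = B.n_rows, n = dQ.n_cols;
  mat A = B - B.t();
  mat Mi = inv(eye(N, N) - A);
  mat C = (eye(N, N) + A) * Mi;
  mat G(N, N, fill::zeros);
  G.cols(0, n - 1) = dQ;
  mat dA = (eye(N, N) + C).t() * G * Mi.t();
  return dA - dA.t();
}

// R-RNG permutation (Fisher-Yates with unif_rand)
inline uvec shuffle_r(uword n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

}  // namespace

// Latent circuit fitting loop. Y (N x K*T pooled, trial-fastest), Z
// (n_out x K*T), U (c x K x T), train: 0-based trial indices.
// win_mask / wout_mask: 0/1 structural masks.
// Returns fitted parameters, the per-epoch loss trace and epoch count.
// [[Rcpp::export]]
Rcpp::List lc_fit_loop(arma::mat B, arma::mat w_rec, arma::mat w_in,
                       arma::mat w_out, const arma::mat& Y,
                       const arma::mat& Z, const arma::cube& U,
                       const arma::uvec& train, const arma::mat& win_mask,
                       const arma::mat& wout_mask, double alpha,
                       double sigma_rec, double lr, double wd,
                       int minibatch, int max_epochs, int patience,
                       double tol, double lambda_orth) {
  const uword n = w_rec.n_rows, K_all = U.n_cols, T = U.n_slices,
              Ktr = train.n_elem;
  const double nsc = sigma_rec > 0 ? std::sqrt(2.0 / alpha) * sigma_rec : 0.0;
  Adam aB(B.n_rows, B.n_cols), aW(n, n), aI(n, w_in.n_cols),
      aO(w_out.n_rows, n);
  long step = 0;
  std::vector<double> trace;
  double best = datum::inf;
  int best_epoch = 0, epoch = 0;
  mat dW(n, n), dWin(n, w_in.n_cols);
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    uvec ord = train(shuffle_r(Ktr));
    double ep_loss = 0;
    for (uword s = 0; s < Ktr; s += minibatch) {
      const uword e = std::min<uword>(s + minibatch, Ktr) - 1;
      const uvec kidx = ord.subvec(s, e);
      const uword Kb = kidx.n_elem;
      // gather minibatch inputs and pooled targets
      cube Ub(U.n_rows, Kb, T);
      for (uword t = 0; t < T; ++t) Ub.slice(t) = U.slice(t).cols(kidx);
      uvec cols(Kb * T);
      for (uword t = 0; t < T; ++t)
        for (uword k = 0; k < Kb; ++k) cols[t * Kb + k] = t * K_all + kidx[k];
      mat Yb = Y.cols(cols), Zb = Z.cols(cols);
      cube X(n, Kb, T + 1), Mg(n, Kb, T);
      sim_forward(w_rec, w_in, Ub, alpha, nsc, X, Mg);
      mat Xp(n, Kb * T);
      for (uword t = 0; t < T; ++t) Xp.cols(t * Kb, t * Kb + Kb - 1) =
        X.slice(t + 1);
      mat Q = cayley_Q(B, n);
      mat R1 = Yb - Q * Xp;
      mat R2 = Zb - w_out * Xp;
      double loss = accu(square(R1)) + accu(square(R2));
      mat dX = -2.0 * (Q.t() * R1) - 2.0 * (w_out.t() * R2);
      cube G(n, Kb, T);
      for (uword t = 0; t < T; ++t) G.slice(t) =
        dX.cols(t * Kb, t * Kb + Kb - 1);
      bptt(w_rec, Ub, X, Mg, G, alpha, dW, dWin);
      mat dQ = -2.0 * (R1 * Xp.t());
      mat dB = cayley_back(B, dQ);
      mat dWout = -2.0 * (R2 * Xp.t());
      if (lambda_orth > 0) {
        mat Bio = join_rows(w_in, w_out.t());
        mat dBio(Bio.n_rows, Bio.n_cols, fill::zeros);
        loss += orth_penalty(Bio, lambda_orth, dBio);
        dWin += dBio.cols(0, w_in.n_cols - 1);
        dWout += dBio.cols(w_in.n_cols, Bio.n_cols - 1).t();
      }
      ++step;
      adam_update(B, dB, aB, lr, wd, step);
      adam_update(w_rec, dW, aW, lr, wd, step);
      adam_update(w_in, dWin, aI, lr, wd, step);
      adam_update(w_out, dWout, aO, lr, wd, step);
      // structural projection: off-structure zeroed, active entries >= 0
      w_in = clamp(w_in % win_mask, 0.0, datum::inf);
      w_out = clamp(w_out % wout_mask, 0.0, datum::inf);
      ep_loss += loss;
    }
    if (!std::isfinite(ep_loss)) Rcpp::stop("latent fit diverged at epoch %d", epoch);
    trace.push_back(ep_loss);
    if (ep_loss < best * (1.0 - tol)) { best = ep_loss; best_epoch = epoch; }
    if (epoch - best_epoch >= patience) break;
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("B") = B, Rcpp::Named("w_rec") = w_rec,
      Rcpp::Named("w_in") = w_in, Rcpp::Named("w_out") = w_out,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("epochs") = (int)trace.size());
}

// RNN task-training loop. Ztar (n_out x K*T pooled targets), mask_kt
// (length K*T, 1 where the output error is penalized), dale: +1/-1 per
// unit (column sign constraint on W_rec).
// [[Rcpp::export]]
Rcpp::List rnn_fit_loop(arma::mat W_rec, arma::mat W_in, arma::mat W_out,
                        const arma::mat& Ztar, const arma::vec& mask_kt,
                        const arma::cube& U, const arma::vec& dale,
                        double alpha, double sigma_rec, double lr, double wd,
                        int minibatch, int max_epochs, int patience,
                        double tol, double lambda_r, double lambda_orth) {
  const uword N = W_rec.n_rows, K_all = U.n_cols, T = U.n_slices;
  const double nsc = sigma_rec > 0 ? std::sqrt(2.0 / alpha) * sigma_rec : 0.0;
  Adam aW(N, N), aI(N, W_in.n_cols), aO(W_out.n_rows, N);
  long step = 0;
  std::vector<double> trace;
  double best = datum::inf;
  int best_epoch = 0, epoch = 0;
  mat dW(N, N), dWin(N, W_in.n_cols);
  const uvec exc = find(dale > 0), inh = find(dale < 0);
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    uvec ord = shuffle_r(K_all);
    double ep_loss = 0;
    for (uword s = 0; s < K_all; s += minibatch) {
      const uword e = std::min<uword>(s + minibatch, K_all) - 1;
      const uvec kidx = ord.subvec(s, e);
      const uword Kb = kidx.n_elem;
      cube Ub(U.n_rows, Kb, T);
      for (uword t = 0; t < T; ++t) Ub.slice(t) = U.slice(t).cols(kidx);
      uvec cols(Kb * T);
      for (uword t = 0; t < T; ++t)
        for (uword k = 0; k < Kb; ++k) cols[t * Kb + k] = t * K_all + kidx[k];
      mat Ztb = Ztar.cols(cols);
      rowvec mb = conv_to<rowvec>::from(mask_kt(cols));
      cube X(N, Kb, T + 1), Mg(N, Kb, T);
      sim_forward(W_rec, W_in, Ub, alpha, nsc, X, Mg);
      mat Yp(N, Kb * T);
      for (uword t = 0; t < T; ++t) Yp.cols(t * Kb, t * Kb + Kb - 1) =
        X.slice(t + 1);
      mat Zb = W_out * Yp;
      const double c_task = (double)Ztb.n_rows * accu(mb);
      const double c_rate = (double)Yp.n_elem;
      mat Rz = Zb - Ztb;
      Rz.each_row() %= mb;
      double loss = accu(square(Rz)) / c_task +
        lambda_r * accu(square(Yp)) / c_rate;
      mat dZ = 2.0 * Rz / c_task;
      mat Gy = W_out.t() * dZ + (2.0 * lambda_r / c_rate) * Yp;
      cube G(N, Kb, T);
      for (uword t = 0; t < T; ++t) G.slice(t) =
        Gy.cols(t * Kb, t * Kb + Kb - 1);
      bptt(W_rec, Ub, X, Mg, G, alpha, dW, dWin);
      mat dWout = dZ * Yp.t();
      if (lambda_orth > 0) {
        mat Bio = join_rows(W_in, W_out.t());
        mat dBio(Bio.n_rows, Bio.n_cols, fill::zeros);
        loss += orth_penalty(Bio, lambda_orth, dBio);
        dWin += dBio.cols(0, W_in.n_cols - 1);
        dWout += dBio.cols(W_in.n_cols, Bio.n_cols - 1).t();
      }
      ++step;
      adam_update(W_rec, dW, aW, lr, wd, step);
      adam_update(W_in, dWin, aI, lr, wd, step);
      adam_update(W_out, dWout, aO, lr, wd, step);
      // Dale projection and nonnegativity
      for (uword j : exc) W_rec.col(j) = clamp(W_rec.col(j), 0.0, datum::inf);
      for (uword j : inh) W_rec.col(j) = clamp(W_rec.col(j), -datum::inf, 0.0);
      W_in = clamp(W_in, 0.0, datum::inf);
      W_out = clamp(W_out, 0.0, datum::inf);
      ep_loss += loss;
    }
    if (!std::isfinite(ep_loss)) Rcpp::stop("training diverged at epoch %d", epoch);
    trace.push_back(ep_loss);
    if (ep_loss < best * (1.0 - tol)) { best = ep_loss; best_epoch = epoch; }
    if (epoch - best_epoch >= patience) break;
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("W_rec") = W_rec, Rcpp::Named("W_in") = W_in,
      Rcpp::Named("W_out") = W_out, Rcpp::Named("trace") = trace,
      Rcpp::Named("epochs") = (int)trace.size());
}
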