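#' Latent circuit objects
#'
#' A latent circuit is a small rectified-linear recurrent circuit of `n`
#' nodes whose trajectories `x`, embedded into `N` dimensions by an
#' orthonormal matrix `Q`, model a high-dimensional response `y = Q x (+ b)`
#' together with behavioral outputs `z = w_out x`. `Q` is parameterized by
#' an auxiliary matrix `B_cayley` through [cayley_embed()]. Node identity is
#' pinned by structural zeros: input `i` feeds node `i` only, and the last
#' two nodes drive the right/left outputs, so fitted circuits are directly
#' comparable without permutation alignment.
#'
#' @param w_rec `n x n` recurrent weights
#' @param w_in `n x n_in` nonnegative input weights (structurally diagonal)
#' @param w_out `n_out x n` nonnegative output weights (choice nodes only)
#' @param B_cayley `N x N` auxiliary matrix parameterizing the embedding
#' @param b optional length-`N` intercept (used for centered neural data)
#' @param alpha Euler step ratio dt/tau
#' @param sigma_rec recurrent noise magnitude
#' @return object of class `latent_circuit`; `$Q` holds the materialized
#'   embedding
#' @export
latent_circuit <- function(w_rec, w_in, w_out, B_cayley, b = NULL,
                           alpha = 0.2, sigma_rec = 0.15) {
  n <- nrow(w_rec)
  lc <- list(w_rec = w_rec, w_in = w_in, w_out = w_out,
             B_cayley = B_cayley, Q = cayley_embed(B_cayley, n),
             b = b, n = n, N = nrow(B_cayley), alpha = alpha,
             sigma_rec = sigma_rec)
  class(lc) <- "latent_circuit"
  lc
}

#' @export
print.latent_circuit <- function(x, ...) {
  cat(sprintf("latent_circuit: n = %d nodes embedded in N = %d dimensions\n",
              x$n, x$N))
  invisible(x)
}

# structural masks fixing node identities: input i -> node i, last n_out
# nodes -> outputs
latent_structure <- function(n, n_in = 6L, n_out = 2L) {
  stopifnot(n >= n_in + n_out)
  win_mask <- matrix(FALSE, n, n_in)
  win_mask[cbind(seq_len(n_in), seq_len(n_in))] <- TRUE
  wout_mask <- matrix(FALSE, n_out, n)
  wout_mask[cbind(seq_len(n_out), n - n_out + seq_len(n_out))] <- TRUE
  list(win_mask = win_mask, wout_mask = wout_mask)
}

# random initialization used for fitting: w_rec uniform centered on 0 with
# sd 1/n, structural entries of w_in/w_out uniform on [0,1], B uniform on
# [0,1]
latent_init <- function(N, n = 8L, seed = 1L, n_in = 6L, n_out = 2L,
                        alpha = 0.2, sigma_rec = 0.15, intercept = FALSE) {
  st <- latent_structure(n, n_in, n_out)
  with_seed_or_not(seed, {
    a <- sqrt(3) / n
    w_rec <- matrix(runif(n * n, -a, a), n, n)
    w_in <- matrix(0, n, n_in); w_in[st$win_mask] <- runif(n_in)
    w_out <- matrix(0, n_out, n); w_out[st$wout_mask] <- runif(n_out)
    B <- matrix(runif(N * N), N, N)
    latent_circuit(w_rec, w_in, w_out, B,
                   b = if (intercept) numeric(N) else NULL,
                   alpha = alpha, sigma_rec = sigma_rec)
  })
}

#' Simulate latent circuit trajectories on a trial batch
#'
#' Same rectified Euler update and noise model as [rnn_simulate()], in `n`
#' dimensions.
#'
#' @param lc a [latent_circuit()]
#' @param batch a `trial_batch`
#' @param seed seed for the recurrent noise
#' @param sigma_rec noise magnitude override
#' @return latent trajectories `x`, trials x time x n
#' @export
simulate_latent <- function(lc, batch, seed = NULL,
                            sigma_rec = lc$sigma_rec) {
  if (dim(batch$u)[3] != ncol(lc$w_in)) {
    stop("batch input channels do not match w_in", call. = FALSE)
  }
  K <- dim(batch$u)[1]
  fw <- with_seed_or_not(seed,
    lc_sim_forward(lc$w_rec, lc$w_in, to_cube(batch$u), lc$alpha, sigma_rec,
                   matrix(0, lc$n, K), array(0, c(0, 0, 0))))
  from_state_cube(fw$Y)
}

#' Latent circuit fitting configuration
#'
#' Adam with learning rate 0.02, weight decay 0.001, moment decays
#' 0.9/0.999, minibatches of 128 trials; optimization stops when the loss
#' has not improved by `tol` over `patience` epochs. `lambda` is the
#' tradeoff weight of the subspace term in the neural-data loss
#' ([fit_neural()]); `lambda_orth` optionally penalizes correlations among
#' the latent input/output vectors (0 = off, matching orthogonally
#' constrained source networks).
#'
#' @param n latent nodes
#' @param learning_rate,weight_decay,minibatch optimizer settings
#' @param max_epochs,patience,tol stopping rule
#' @param lambda neural-data tradeoff weight
#' @param lambda_orth input/output orthogonality penalty weight
#' @param seed governs the train/test split, initialization and noise
#' @return a list of class `latent_fit_config`
#' @export
latent_fit_config <- function(n = 8L, learning_rate = 0.02,
                              weight_decay = 0.001, minibatch = 128L,
                              max_epochs = 400L, patience = 25L,
                              tol = 0.001, lambda = 0.5, lambda_orth = 0,
                              sigma_rec = 0.15, seed = 1L) {
  structure(as.list(environment()), class = "latent_fit_config")
}

# 50/50 split by trial within each condition
split_trials <- function(conditions, seed) {
  key <- interaction(conditions$context, conditions$motion_coherence,
                     conditions$color_coherence, drop = TRUE)
  with_seed_or_not(seed, {
    train <- logical(nrow(conditions))
    for (lev in levels(key)) {
      idx <- which(key == lev)
      idx <- sample(idx)
      train[idx[seq_len(ceiling(length(idx) / 2))]] <- TRUE
    }
    list(train = which(train), test = which(!train))
  })
}

#' Fit a latent circuit to response data
#'
#' Minimizes the mean squared reconstruction error
#' `sum ||y - Q x||^2 + ||z - w_out x||^2` over trials and time (normalized
#' per trial-timestep), jointly over the embedding parameterization
#' `B_cayley`, the latent connectivity `w_rec`, `w_in` and the readout
#' `w_out`, by Adam with backpropagation through the latent dynamics and
#' the Cayley transform. Latent trajectories are re-simulated with fresh
#' recurrent noise on every minibatch. After each update the structural
#' zeros of `w_in`/`w_out` are re-imposed and their active entries clamped
#' nonnegative.
#'
#' Trials are split 50/50 within each condition; fit metrics are computed
#' on the held-out half only.
#'
#' @param y responses, trials x time x N
#' @param z behavioral outputs to reproduce, trials x time x 2 (for source
#'   networks, their actual outputs)
#' @param batch the `trial_batch` the responses were generated from
#' @param cfg a [latent_fit_config()]
#' @param init optional `latent_circuit` to start from (default: random
#'   initialization from `cfg$seed`)
#' @param split optional list with `train`/`test` trial indices, e.g. to
#'   share one split across an ensemble
#' @return a `latent_fit` object: fitted `circuit`, per-epoch `loss_trace`,
#'   held-out `metrics` (`r2_total`, residual ratios `r_q2`, `r_x2`,
#'   `r_z2`, and `task_r2`), the `split`, and the initialization seed
#' @export
fit_latent <- function(y, z, batch, cfg = latent_fit_config(), init = NULL,
                       split = NULL) {
  N <- dim(y)[3]
  if (cfg$n > N) stop("n must not exceed the response dimension", call. = FALSE)
  if (dim(y)[1] != dim(batch$u)[1]) {
    stop("responses and batch have different trial counts", call. = FALSE)
  }
  if (is.null(split)) split <- split_trials(batch$conditions, cfg$seed)
  lc <- if (is.null(init)) {
    latent_init(N, cfg$n, seed = cfg$seed, alpha = batch$alpha,
                sigma_rec = cfg$sigma_rec)
  } else init
  st <- latent_structure(lc$n, ncol(lc$w_in), nrow(lc$w_out))
  # the whole minibatch-Adam loop runs in compiled code; the equivalent R
  # step functions (latent_loss_grad / adam_step) remain the tested
  # reference implementation
  res <- with_seed_or_not(cfg$seed + 1L,
    lc_fit_loop(lc$B_cayley, lc$w_rec, lc$w_in, lc$w_out,
                pool_mat(y), pool_mat(z), to_cube(batch$u),
                split$train - 1L, st$win_mask * 1, st$wout_mask * 1,
                lc$alpha, lc$sigma_rec, cfg$learning_rate,
                cfg$weight_decay, cfg$minibatch, cfg$max_epochs,
                cfg$patience, cfg$tol, cfg$lambda_orth))
  lc <- latent_circuit(res$w_rec, res$w_in, res$w_out, res$B,
                       alpha = lc$alpha, sigma_rec = lc$sigma_rec)
  metrics <- latent_fit_metrics(lc, y, z, batch, split$test,
                                seed = cfg$seed + 2L)
  structure(list(circuit = lc, loss_trace = res$trace,
                 final_loss = res$trace[length(res$trace)],
                 metrics = metrics, split = split, seed = cfg$seed,
                 epochs = res$epochs),
            class = "latent_fit")
}

#' @export
print.latent_fit <- function(x, ...) {
  cat(sprintf(
    "latent_fit: n = %d, %d epochs, held-out r2 = %.3f (task r2 = %.3f)\n",
    x$circuit$n, x$epochs, x$metrics$r2_total, x$metrics$task_r2))
  invisible(x)
}

# loss and gradients of the reconstruction objective on one minibatch;
# `pooled` carries the pre-pooled response/output matrices and input cube
latent_loss_grad <- function(theta, lc, pooled, kidx, cfg) {
  K <- length(kidx); Tn <- pooled$Tn; n <- lc$n
  cols <- rep(kidx, times = Tn) + rep((seq_len(Tn) - 1L) * pooled$K_all,
                                      each = K)
  U <- pooled$U[, kidx, , drop = FALSE]
  fw <- lc_sim_forward(theta$w_rec, theta$w_in, U, lc$alpha, lc$sigma_rec,
                       matrix(0, n, K), array(0, c(0, 0, 0)))
  X <- matrix(fw$Y[, , -1L], n, K * Tn)
  Q <- cayley_embed(theta$B, n)
  Ymat <- pooled$Y[, cols, drop = FALSE]
  Zmat <- pooled$Z[, cols, drop = FALSE]
  R1 <- Ymat - Q %*% X
  R2 <- Zmat - theta$w_out %*% X
  # plain summed squared-error loss (see rnn_loss_grad for the rationale)
  loss <- sum(R1^2) + sum(R2^2)
  dX <- -2 * crossprod(Q, R1) - 2 * crossprod(theta$w_out, R2)
  bp <- lc_bptt(theta$w_rec, theta$w_in, U, fw$Y, fw$M,
                array(dX, c(n, K, Tn)), lc$alpha)
  dQ <- -2 * (R1 %*% t(X))
  grads <- list(B = cayley_backward(theta$B, dQ),
                w_rec = bp$dW, w_in = bp$dWin,
                w_out = -2 * (R2 %*% t(X)))
  if (cfg$lambda_orth > 0) {
    op <- orth_penalty(cbind(theta$w_in, t(theta$w_out)), cfg$lambda_orth)
    loss <- loss + op$value
    n_in <- ncol(theta$w_in)
    grads$w_in <- grads$w_in + op$grad[, seq_len(n_in)]
    grads$w_out <- grads$w_out + t(op$grad[, n_in + seq_len(nrow(theta$w_out))])
  }
  list(loss = loss, grads = grads)
}

# Held-out fit quality. r2_total is the pooled coefficient of
# determination between the embedded model trajectory and the data, both
# averaged within condition over the held-out trials (the two disjoint
# trial sets of the cross-validation protocol are compared as condition
# averages); the model trajectory is simulated without recurrent noise, so
# metrics compare the data to the model's mean prediction rather than one
# stochastic realization. The residual ratios and task performance are
# pooled per trial.
latent_fit_metrics <- function(lc, y, z, batch, test_idx, seed = 1L) {
  sub <- subset_batch(batch, test_idx)
  x <- simulate_latent(lc, sub, seed = seed, sigma_rec = 0)
  Ymat <- pool_mat(y[test_idx, , , drop = FALSE])
  Zmat <- pool_mat(z[test_idx, , , drop = FALSE])
  X <- pool_mat(x)
  b <- if (is.null(lc$b)) 0 else lc$b
  Yhat <- lc$Q %*% X + b
  Zhat <- lc$w_out %*% X
  QtY <- crossprod(lc$Q, Ymat)
  msel <- as.numeric(sub$mask)
  Ztar <- pool_mat(sub$z_target)
  sel <- rep(msel > 0, each = nrow(Ztar))
  key <- droplevels(interaction(sub$conditions$context,
                                sub$conditions$motion_coherence,
                                sub$conditions$color_coherence))
  list(r2_total = r_squared(condition_average(y[test_idx, , , drop = FALSE],
                                              key),
                            condition_average(from_prediction(Yhat, x), key)),
       r_q2 = ss_ratio(Ymat - lc$Q %*% QtY, Ymat),
       r_x2 = ss_ratio(crossprod(lc$Q, Ymat - b) - X, QtY),
       r_z2 = ss_ratio(Zmat - Zhat, Zmat),
       task_r2 = r_squared(Ztar[sel], Zhat[sel]))
}

# reshape a pooled N x (K*T) prediction back to [K,T,N] (x supplies dims)
from_prediction <- function(Yhat, x) {
  d <- dim(x)
  aperm(array(Yhat, c(nrow(Yhat), d[1], d[2])), c(2L, 3L, 1L))
}

# average a [K,T,N] array within condition groups
condition_average <- function(a, key) {
  out <- array(0, c(nlevels(key), dim(a)[2], dim(a)[3]))
  for (i in seq_len(nlevels(key))) {
    rows <- which(key == levels(key)[i])
    out[i, , ] <- apply(a[rows, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

# restrict a trial_batch to a subset of trials
subset_batch <- function(batch, idx) {
  out <- batch
  out$u <- batch$u[idx, , , drop = FALSE]
  out$z_target <- batch$z_target[idx, , , drop = FALSE]
  out$mask <- batch$mask[idx, , drop = FALSE]
  out$conditions <- batch$conditions[idx, , drop = FALSE]
  out
}

#' Fit an ensemble of latent circuits and keep the best
#'
#' Runs `n_inits` independent fits from distinct random initializations
#' (all sharing one train/test split) and returns the `top_k` fits ranked
#' by held-out `r2_total`, ties broken by lower final training loss.
#' Nonconvex optimization makes individual runs land in solutions of
#' variable quality; the converged top of the ensemble is what supports
#' interpretation.
#'
#' @inheritParams fit_latent
#' @param n_inits number of independent fits
#' @param top_k number of best fits to return
#' @return list of `latent_fit` objects, best first
#' @export
fit_ensemble <- function(y, z, batch, n_inits = 20L, top_k = 10L,
                         cfg = latent_fit_config()) {
  if (n_inits < top_k) stop("n_inits must be >= top_k", call. = FALSE)
  split <- split_trials(batch$conditions, cfg$seed)
  fits <- vector("list", n_inits)
  for (i in seq_len(n_inits)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 1000L * i
    fits[[i]] <- tryCatch(
      fit_latent(y, z, batch, cfg_i, split = split),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all ensemble fits failed", call. = FALSE)
  r2 <- vapply(fits, function(f) f$metrics$r2_total, numeric(1))
  fl <- vapply(fits, function(f) f$final_loss, numeric(1))
  fits[order(-r2, fl)][seq_len(min(top_k, length(fits)))]
}
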