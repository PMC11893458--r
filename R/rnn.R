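#' Initialize a Dale-constrained rectified-linear RNN
#'
#' Units are split into excitatory and inhibitory populations (80/20 by
#' default). Excitatory recurrent weights are drawn from a Gaussian with
#' mean `1/sqrt(N)` and variance `1/N`, inhibitory weights from a Gaussian
#' with mean `4/sqrt(N)` and variance `1/N` (sign applied to the whole
#' column); draws that would violate Dale's law are clipped to zero. The
#' recurrent matrix is then rescaled to the requested spectral radius.
#' Input weights are drawn uniformly on `[0, 1]` -- strong enough that
#' every input, including the transient context cue, reaches the recurrent
#' population from the first gradient step -- and output weights are drawn
#' uniformly on
#' `[0, 1/sqrt(N)]`.
#'
#' @param N number of units (the excitatory fraction must divide N evenly)
#' @param seed integer seed
#' @param exc_frac excitatory fraction
#' @param spectral_radius target spectral radius of `W_rec` after scaling
#' @param tau membrane time constant, ms
#' @param dt simulation timestep, ms
#' @param sigma_rec recurrent noise magnitude
#' @return an `rnn_params` object with `W_rec` (N x N), `W_in` (N x 6),
#'   `W_out` (2 x N), `dale_sign` (+1/-1 per unit), and simulation constants
#' @export
rnn_init <- function(N = 50L, seed = 1L, exc_frac = 0.8,
                     spectral_radius = 1.5, tau = 200, dt = 40,
                     sigma_rec = 0.15) {
  n_exc <- round(N * exc_frac)
  if (N < 2L || abs(n_exc - N * exc_frac) > 1e-9) {
    stop("excitatory/inhibitory split must divide N evenly", call. = FALSE)
  }
  dale_sign <- rep(c(1, -1), c(n_exc, N - n_exc))
  with_seed_or_not(seed, {
    W <- matrix(rnorm(N * N, mean = 1 / sqrt(N), sd = 1 / sqrt(N)), N, N)
    W[, dale_sign < 0] <- matrix(
      rnorm(N * (N - n_exc), mean = 4 / sqrt(N), sd = 1 / sqrt(N)),
      N, N - n_exc)
    W <- pmax(W, 0) * rep(dale_sign, each = N)
    W <- W * spectral_radius / max(Mod(eigen(W, only.values = TRUE)$values))
    W_in <- matrix(runif(N * 6), N, 6)
    W_out <- matrix(runif(2 * N, 0, 1 / sqrt(N)), 2, N)
    structure(list(W_rec = W, W_in = W_in, W_out = W_out,
                   dale_sign = dale_sign, N = N, tau = tau, dt = dt,
                   alpha = dt / tau, sigma_rec = sigma_rec, seed = seed),
              class = "rnn_params")
  })
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("rnn_params: N = %d (%d excitatory), tau = %g ms, dt = %g ms, sigma_rec = %g\n",
              x$N, sum(x$dale_sign > 0), x$tau, x$dt, x$sigma_rec))
  invisible(x)
}

#' Simulate RNN responses on a trial batch
#'
#' First-order Euler update with rectification:
#' `y_t = (1-alpha) y_{t-1} + alpha * relu(W_rec y_{t-1} + W_in u_t + noise)`
#' with noise sd `sqrt(2/alpha) * sigma_rec` inside the rectifier. Responses
#' are nonnegative at all times. Deterministic given `seed`.
#'
#' @param params an [rnn_init()] object
#' @param batch a `trial_batch`
#' @param seed seed for the recurrent noise (`NULL` = use current RNG state)
#' @param sigma_rec override of the noise magnitude (e.g. 0 for noiseless)
#' @param ext optional external current, trials x time x N, injected inside
#'   the rectifier (used for activity stimulation probes)
#' @return list with `y` (trials x time x N) and outputs `z`
#'   (trials x time x 2, `z = W_out y`)
#' @export
rnn_simulate <- function(params, batch, seed = NULL,
                         sigma_rec = params$sigma_rec, ext = NULL) {
  if (dim(batch$u)[3] != ncol(params$W_in)) {
    stop("batch input channels do not match W_in", call. = FALSE)
  }
  K <- dim(batch$u)[1]
  Ext <- if (is.null(ext)) array(0, c(0, 0, 0)) else to_cube(ext)
  fw <- with_seed_or_not(seed,
    lc_sim_forward(params$W_rec, params$W_in, to_cube(batch$u),
                   params$alpha, sigma_rec, matrix(0, params$N, K), Ext))
  y <- from_state_cube(fw$Y)
  z <- apply_readout(params$W_out, y)
  list(y = y, z = z)
}

# z = W_out y for a [K,T,N] response array -> [K,T,2]
apply_readout <- function(W_out, y) {
  d <- dim(y)
  zm <- W_out %*% pool_mat(y)
  aperm(array(zm, c(nrow(W_out), d[1], d[2])), c(2L, 3L, 1L))
}

#' RNN training configuration
#'
#' Defaults follow the reference training setup: Adam with learning rate
#' 0.01, weight decay 0.001, moment decays 0.9/0.999, minibatches of 128
#' trials, 1,800 training trials, a firing-rate penalty `lambda_r = 0.05`
#' and an input/output orthogonality penalty `lambda_orth = 1`. Training
#' stops when the epoch loss has not improved by `tol` for `patience`
#' epochs, or at `max_epochs`.
#'
#' @param learning_rate,weight_decay,minibatch,n_trials,lambda_r,lambda_orth
#'   optimizer and loss hyperparameters
#' @param max_epochs,patience,tol stopping rule
#' @param seed seed governing the training batch, minibatch order and noise
#' @return a list of class `rnn_train_config`
#' @export
rnn_train_config <- function(learning_rate = 0.01, weight_decay = 0.001,
                             minibatch = 128L, n_trials = 1800L,
                             lambda_r = 0.05, lambda_orth = 1,
                             max_epochs = 200L, patience = 25L, tol = 0.001,
                             seed = 1L) {
  structure(as.list(environment()), class = "rnn_train_config")
}

#' Train an RNN on the context-dependent decision-making task
#'
#' Minimizes the masked mean squared output error plus a firing-rate
#' penalty and an orthogonality penalty on the column-normalized
#' concatenation of `W_in` and `t(W_out)`, using Adam with
#' backpropagation through time. After every update, recurrent weights that
#' changed sign against Dale's law are clipped to zero and input/output
#' weights are clamped nonnegative. Fresh recurrent noise is drawn for
#' every minibatch.
#'
#' @param params an [rnn_init()] object
#' @param cfg an [rnn_train_config()]
#' @param task a [ctx_dm_task()]
#' @param conditions condition set to sample trials from
#' @param verbose print the loss every 25 epochs
#' @return list with the trained `params`, the per-epoch `loss_trace` and
#'   `epochs` run
#' @export
rnn_train <- function(params, cfg = rnn_train_config(),
                      task = ctx_dm_task(),
                      conditions = ctx_dm_conditions(), verbose = FALSE) {
  n_per <- ceiling(cfg$n_trials / nrow(conditions))
  batch <- make_batch(conditions, n_per, seed = cfg$seed, task = task,
                      alpha = params$alpha)
  K <- dim(batch$u)[1]
  run_loop <- function(theta, batch, epochs) {
    # whole minibatch-Adam loop in compiled code; rnn_loss_grad/adam_step
    # remain the tested R reference
    rnn_fit_loop(theta$W_rec, theta$W_in, theta$W_out,
                 t(matrix(batch$z_target, K * dim(batch$u)[2], 2)),
                 as.numeric(batch$mask), to_cube(batch$u),
                 params$dale_sign, params$alpha, params$sigma_rec,
                 cfg$learning_rate, cfg$weight_decay, cfg$minibatch,
                 epochs, cfg$patience, cfg$tol, cfg$lambda_r,
                 cfg$lambda_orth)
  }
  theta <- params[c("W_rec", "W_in", "W_out")]
  res <- with_seed_or_not(cfg$seed + 1L,
                          run_loop(theta, batch, cfg$max_epochs))
  params[c("W_rec", "W_in", "W_out")] <- res[c("W_rec", "W_in", "W_out")]
  if (verbose) {
    message(sprintf("stopped after %d epochs, loss %.4f", res$epochs,
                    res$trace[res$epochs]))
  }
  list(params = params, loss_trace = res$trace, epochs = res$epochs)
}

# loss and gradients for one minibatch (noise drawn from the current RNG)
rnn_loss_grad <- function(theta, params, batch, kidx, cfg) {
  U <- to_cube(batch$u[kidx, , , drop = FALSE])
  K <- length(kidx); Tn <- dim(U)[3]; N <- params$N
  fw <- lc_sim_forward(theta$W_rec, theta$W_in, U, params$alpha,
                       params$sigma_rec, matrix(0, N, K),
                       array(0, c(0, 0, 0)))
  Ymat <- matrix(fw$Y[, , -1L], N, K * Tn)       # unit x (trial,time)
  Z <- theta$W_out %*% Ymat
  Ztar <- t(matrix(batch$z_target[kidx, , , drop = FALSE], K * Tn, 2))
  mvec <- as.numeric(batch$mask[kidx, , drop = FALSE])  # trial-fastest
  # mean-reduction loss: masked squared output error averaged over the
  # penalized entries plus lambda_r times the mean squared rate. Adam is
  # scale-invariant, so only the relative weight of the terms matters;
  # averaging each term over its own support keeps the rate penalty gentle
  # enough that persistent (memory) activity is not priced out.
  c_task <- 2 * sum(mvec)
  c_rate <- length(Ymat)
  dZ <- 2 * (Z - Ztar) * rep(mvec, each = 2) / c_task
  task_loss <- sum((Z - Ztar)^2 * rep(mvec, each = 2)) / c_task
  rate_loss <- cfg$lambda_r * sum(Ymat^2) / c_rate
  Gy <- crossprod(theta$W_out, dZ) + 2 * cfg$lambda_r * Ymat / c_rate
  bp <- lc_bptt(theta$W_rec, theta$W_in, U, fw$Y, fw$M,
                array(Gy, c(N, K, Tn)), params$alpha)
  dW_out <- dZ %*% t(Ymat)
  op <- orth_penalty(cbind(theta$W_in, t(theta$W_out)), cfg$lambda_orth)
  list(loss = task_loss + rate_loss + op$value,
       grads = list(W_rec = bp$dW,
                    W_in = bp$dWin + op$grad[, 1:6],
                    W_out = dW_out + t(op$grad[, 7:8])))
}

#' Read out choices from network outputs
#'
#' The choice is the sign of the difference between the two output units at
#' the final step of each trial: right if `z_right > z_left`. Exact ties are
#' broken by a seeded fair coin and flagged in the `ties` attribute.
#'
#' @param z outputs, trials x time x 2
#' @param seed seed for tie-breaking
#' @return character vector of `"right"`/`"left"` with a logical `ties`
#'   attribute marking tie-broken trials
#' @export
decide <- function(z, seed = 1L) {
  Tn <- dim(z)[2]
  d <- z[, Tn, 1] - z[, Tn, 2]
  ties <- d == 0
  choice <- ifelse(d > 0, "right", "left")
  if (any(ties)) {
    choice[ties] <- with_seed_or_not(seed,
      sample(c("right", "left"), sum(ties), replace = TRUE))
  }
  attr(choice, "ties") <- ties
  choice
}

#' Psychometric table of an RNN
#'
#' Simulates fresh noisy trials for every condition and tabulates the
#' fraction of rightward choices per combination of context, motion
#' coherence and color coherence.
#'
#' @param params an `rnn_params` object
#' @param n_per_condition trials per condition
#' @param seed seed for input noise, recurrent noise and tie-breaking
#' @param task,conditions task definition and condition set
#' @param ext optional stimulation current forwarded to [rnn_simulate()]
#'   (trials x time x N, or a function(batch) producing it)
#' @return data frame: condition columns plus `frac_right` and `n_trials`
#' @export
psychometric <- function(params, n_per_condition = 20L, seed = 1L,
                         task = ctx_dm_task(),
                         conditions = ctx_dm_conditions(), ext = NULL) {
  batch <- make_batch(conditions, n_per_condition, seed = seed, task = task,
                      alpha = params$alpha)
  if (is.function(ext)) ext <- ext(batch)
  sim <- rnn_simulate(params, batch, seed = seed + 1L, ext = ext)
  choice <- decide(sim$z, seed = seed + 2L)
  right <- as.integer(choice == "right")
  agg <- stats::aggregate(
    right,
    by = batch$conditions[c("context", "motion_coherence", "color_coherence")],
    FUN = function(v) c(mean(v), length(v)))
  out <- agg[1:3]
  out$frac_right <- agg$x[, 1]
  out$n_trials <- as.integer(agg$x[, 2])
  out
}

#' Task performance of an RNN
#'
#' Coefficient of determination between outputs and targets over the
#' penalized epochs of a fresh test batch.
#'
#' @inheritParams psychometric
#' @return scalar r^2
#' @export
rnn_task_r2 <- function(params, n_per_condition = 5L, seed = 1234L,
                        task = ctx_dm_task(),
                        conditions = ctx_dm_conditions()) {
  batch <- make_batch(conditions, n_per_condition, seed = seed, task = task,
                      alpha = params$alpha)
  sim <- rnn_simulate(params, batch, seed = seed + 1L)
  sel <- array(batch$mask, dim(batch$z_target)[c(1, 2)])
  sel <- array(rep(sel, 2), dim(batch$z_target))
  r_squared(batch$z_target[sel], sim$z[sel])
}
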