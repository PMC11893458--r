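#' Fit a latent circuit to condition-averaged firing-rate data
#'
#' Fits the model `y = Q x + b`, `z = w_out x` to a [rate_population()]
#' with the normalized three-term loss
#' `L = lambda * r_Q2 + r_x2 + r_z2`, where `r_Q2` is the squared residual
#' of projecting the data onto the embedding subspace (relative to the total
#' sum of squares), `r_x2` the squared mismatch between the projected,
#' centered data and the latent trajectories (relative to the projected sum
#' of squares) and `r_z2` the squared output error on the penalized steps
#' (relative to the target sum of squares). `lambda` balances how much of
#' the population variance the subspace must capture against the quality of
#' the dynamical fit within it; it matters when the task-relevant variance
#' is a small fraction of the total, as in cortical recordings.
#'
#' Data terms are evaluated only on timesteps with observed responses; the
#' output term only within the response window. Each condition average is
#' treated as one trial. Metrics are computed against the population's
#' held-out split.
#'
#' @param pop a [rate_population()]
#' @param cfg a [latent_fit_config()]; `cfg$lambda` sets the tradeoff
#' @param init optional starting `latent_circuit` (with intercept)
#' @return a `latent_fit` object whose circuit carries the intercept `b`
#' @export
fit_neural <- function(pop, cfg = latent_fit_config(), init = NULL) {
  task <- pop$task
  batch <- make_batch(pop$conditions, 1L, seed = cfg$seed, task = task,
                      sigma_in = 0, alpha = pop$alpha)
  N <- dim(pop$rates)[3]
  if (cfg$n > N) stop("n must not exceed the response dimension", call. = FALSE)
  lc <- if (is.null(init)) {
    latent_init(N, cfg$n, seed = cfg$seed, alpha = pop$alpha,
                sigma_rec = cfg$sigma_rec, intercept = TRUE)
  } else init
  st <- latent_structure(lc$n, ncol(lc$w_in), nrow(lc$w_out))
  theta <- list(B = lc$B_cayley, w_rec = lc$w_rec, w_in = lc$w_in,
                w_out = lc$w_out, b = matrix(lc$b, ncol = 1))
  state <- adam_init(theta)
  trace <- numeric(0); best <- Inf; best_epoch <- 0L
  with_seed_or_not(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      gl <- neural_loss_grad(theta, lc, pop, batch, cfg)
      upd <- adam_step(theta, gl$grads, state, cfg$learning_rate,
                       cfg$weight_decay)
      theta <- upd$params; state <- upd$state
      theta$w_in[!st$win_mask] <- 0
      theta$w_in[st$win_mask] <- pmax(theta$w_in[st$win_mask], 0)
      theta$w_out[!st$wout_mask] <- 0
      theta$w_out[st$wout_mask] <- pmax(theta$w_out[st$wout_mask], 0)
      if (!is.finite(gl$loss)) {
        stop(sprintf("neural fit diverged at epoch %d", epoch), call. = FALSE)
      }
      trace <- c(trace, gl$loss)
      if (gl$loss < best * (1 - cfg$tol)) { best <- gl$loss; best_epoch <- epoch }
      if (epoch - best_epoch >= cfg$patience) break
    }
  })
  lc <- latent_circuit(theta$w_rec, theta$w_in, theta$w_out, theta$B,
                       b = as.numeric(theta$b), alpha = lc$alpha,
                       sigma_rec = lc$sigma_rec)
  metrics <- neural_fit_metrics(lc, pop, batch, cfg, seed = cfg$seed + 2L)
  structure(list(circuit = lc, loss_trace = trace,
                 final_loss = trace[length(trace)], metrics = metrics,
                 split = list(train = "rates", test = "rates_test"),
                 seed = cfg$seed, epochs = length(trace)),
            class = "latent_fit")
}

# loss and gradients of the three-term normalized objective (full batch)
neural_loss_grad <- function(theta, lc, pop, batch, cfg) {
  U <- to_cube(batch$u)
  K <- dim(U)[2]; Tn <- dim(U)[3]; n <- lc$n
  obs <- pop$observed_steps
  fw <- lc_sim_forward(theta$w_rec, theta$w_in, U, lc$alpha, lc$sigma_rec,
                       matrix(0, n, K), array(0, c(0, 0, 0)))
  Q <- cayley_embed(theta$B, n)
  b <- theta$b
  # observed-step pooling: columns ordered (trial fastest, then time)
  Xo <- matrix(fw$Y[, , obs + 1L, drop = FALSE], n, K * length(obs))
  Yo <- pool_mat(pop$rates)                     # N x (K * n_observed)
  # subspace term
  Dy <- sum(Yo^2)
  QtY <- crossprod(Q, Yo)
  r_q2 <- (Dy - sum(QtY^2)) / Dy
  YYtQ <- Yo %*% t(QtY)                          # (Yo Yo^T) Q
  dQ <- cfg$lambda * (-2) * YYtQ / Dy
  # projected-fit term
  Rx <- crossprod(Q, Yo - c(b)) - Xo
  Dqy <- sum(QtY^2)
  num_x <- sum(Rx^2)
  r_x2 <- num_x / Dqy
  dQ <- dQ + 2 * (Yo - c(b)) %*% t(Rx) / Dqy - num_x * 2 * YYtQ / Dqy^2
  db <- matrix(-2 * (Q %*% rowSums(Rx)) / Dqy, ncol = 1)
  # task term on masked steps
  msk <- which(batch$mask[1, ])
  Xm <- matrix(fw$Y[, , msk + 1L, drop = FALSE], n, K * length(msk))
  Ztar <- matrix(aperm(batch$z_target[, msk, , drop = FALSE], c(3, 1, 2)),
                 2, K * length(msk))
  Rz <- Ztar - theta$w_out %*% Xm
  Dz <- sum(Ztar^2)
  r_z2 <- sum(Rz^2) / Dz
  # upstream gradients on latent states
  G <- array(0, c(n, K, Tn))
  G[, , obs] <- array(-2 * Rx / Dqy, c(n, K, length(obs)))
  G[, , msk] <- G[, , msk] +
    array(-2 * crossprod(theta$w_out, Rz) / Dz, c(n, K, length(msk)))
  bp <- lc_bptt(theta$w_rec, theta$w_in, U, fw$Y, fw$M, G, lc$alpha)
  list(loss = cfg$lambda * r_q2 + r_x2 + r_z2,
       grads = list(B = cayley_backward(theta$B, dQ),
                    w_rec = bp$dW, w_in = bp$dWin,
                    w_out = -2 * (Rz %*% t(Xm)) / Dz, b = db),
       terms = c(r_q2 = r_q2, r_x2 = r_x2, r_z2 = r_z2))
}

# held-out metrics against the population's second split (deterministic
# model trajectory; see latent_fit_metrics)
neural_fit_metrics <- function(lc, pop, batch, cfg, seed = 1L) {
  x <- simulate_latent(lc, batch, seed = seed, sigma_rec = 0)
  obs <- pop$observed_steps
  Xo <- pool_mat(x[, obs, , drop = FALSE])
  Yo <- pool_mat(pop$rates_test)
  Yhat <- lc$Q %*% Xo + lc$b
  QtY <- crossprod(lc$Q, Yo)
  msk <- which(batch$mask[1, ])
  Zhat <- pool_mat_readout(lc$w_out, x, msk)
  Ztar <- matrix(aperm(batch$z_target[, msk, , drop = FALSE], c(3, 1, 2)),
                 2, length(msk) * dim(x)[1])
  list(r2_total = r_squared(Yo, Yhat),
       r_q2 = ss_ratio(Yo - lc$Q %*% QtY, Yo),
       r_x2 = ss_ratio(crossprod(lc$Q, Yo - lc$b) - Xo, QtY),
       r_z2 = ss_ratio(Ztar - Zhat, Ztar),
       task_r2 = r_squared(Ztar, Zhat))
}

pool_mat_readout <- function(w_out, x, steps) {
  Xm <- pool_mat(x[, steps, , drop = FALSE])
  w_out %*% Xm
}

#' Grid search over the subspace tradeoff weight
#'
#' Refits [fit_neural()] for each value of `lambda` and tabulates the
#' held-out metrics, replicating the selection logic of maximizing the
#' subspace and dynamical fit subject to good task performance.
#'
#' @param pop a [rate_population()]
#' @param lambdas grid of tradeoff weights
#' @param cfg base [latent_fit_config()]
#' @return data frame of `lambda` and held-out metrics
#' @export
lambda_grid <- function(pop, lambdas = seq(0, 1.5, by = 0.25),
                        cfg = latent_fit_config()) {
  rows <- lapply(lambdas, function(l) {
    cfg$lambda <- l
    f <- fit_neural(pop, cfg)
    data.frame(lambda = l, r2_total = f$metrics$r2_total,
               r_q2 = f$metrics$r_q2, r_x2 = f$metrics$r_x2,
               r_z2 = f$metrics$r_z2, task_r2 = f$metrics$task_r2)
  })
  do.call(rbind, rows)
}
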