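test_that("initialization respects the Dale architecture and spectral radius", {
  p <- rnn_init(N = 50, seed = 3)
  expect_equal(sum(p$dale_sign > 0), 40)
  expect_equal(sum(p$dale_sign < 0), 10)
  expect_true(all(p$W_rec[, p$dale_sign > 0] >= 0))
  expect_true(all(p$W_rec[, p$dale_sign < 0] <= 0))
  expect_true(all(p$W_in >= 0) && all(p$W_out >= 0))
  rho <- max(Mod(eigen(p$W_rec, only.values = TRUE)$values))
  expect_equal(rho, 1.5, tolerance = 1e-6)
  expect_identical(rnn_init(N = 50, seed = 3), p)
  expect_error(rnn_init(N = 3), "split")
})

test_that("the Euler update matches hand-computed and linear-system oracles", {
  # single unit, constant drive: y1 = 0.2, y2 = 0.38
  p <- unit_rnn()
  batch <- list(u = array(1, c(1, 2, 1)))
  y <- rnn_simulate(p, batch, sigma_rec = 0)$y
  expect_equal(as.numeric(y[1, , 1]), c(0.2, 0.38))
  # no drive, no noise: the origin is a fixed point
  p0 <- rnn_init(N = 10, seed = 8)
  b0 <- tiny_batch(sigma_in = 0)
  b0$u[] <- 0
  expect_true(all(rnn_simulate(p0, b0, sigma_rec = 0)$y == 0))
  # all-positive preactivations: equals the linear recursion computed in R
  set.seed(21)
  N <- 4
  pl <- structure(list(W_rec = matrix(runif(N * N, 0, 0.2), N),
                       W_in = matrix(runif(N * 6, 0, 0.5), N),
                       W_out = matrix(1, 2, N), dale_sign = rep(1, N),
                       N = N, tau = 200, dt = 40, alpha = 0.2,
                       sigma_rec = 0), class = "rnn_params")
  bl <- tiny_batch(n_per = 1, sigma_in = 0)
  y <- rnn_simulate(pl, bl, sigma_rec = 0)$y
  for (k in c(1, 40)) {
    yk <- rep(0, N)
    for (t in seq_len(dim(bl$u)[2])) {
      a <- pl$W_rec %*% yk + pl$W_in %*% bl$u[k, t, ]
      expect_true(all(a > 0))
      yk <- 0.8 * yk + 0.2 * a
      expect_equal(as.numeric(y[k, t, ]), as.numeric(yk), tolerance = 1e-12)
    }
  }
  # responses stay nonnegative under noise, and noise is seed-reproducible
  pn <- rnn_init(N = 10, seed = 12)
  bn <- tiny_batch()
  y1 <- rnn_simulate(pn, bn, seed = 5)$y
  y2 <- rnn_simulate(pn, bn, seed = 5)$y
  expect_identical(y1, y2)
  expect_true(min(y1) >= 0)
})

test_that("backpropagation-through-time gradients match finite differences", {
  set.seed(77)
  p <- rnn_init(N = 5, seed = 1)
  p$sigma_rec <- 0
  theta <- p[c("W_rec", "W_in", "W_out")]
  batch <- make_batch(ctx_dm_conditions()[c(1, 30, 50, 70), ], 1, seed = 3,
                      task = ctx_dm_task(dt_ms = 500), sigma_in = 0.05)
  cfg <- rnn_train_config(lambda_r = 0.05, lambda_orth = 0.5)
  lg <- latentcircuit:::rnn_loss_grad
  f <- function(th) lg(th, p, batch, 1:4, cfg)$loss
  gl <- lg(theta, p, batch, 1:4, cfg)
  eps <- 1e-6
  for (nm in names(theta)) {
    gnum <- theta[[nm]] * 0
    for (i in seq_along(gnum)) {
      tp <- theta; tp[[nm]][i] <- tp[[nm]][i] + eps
      tm <- theta; tm[[nm]][i] <- tm[[nm]][i] - eps
      gnum[i] <- (f(tp) - f(tm)) / (2 * eps)
    }
    expect_lt(max(abs(gnum - gl$grads[[nm]])) / max(abs(gnum)), 1e-5)
  }
})

test_that("choices follow the output sign rule with flagged tie-breaking", {
  z <- array(0, c(3, 2, 2))
  z[1, 2, ] <- c(1.1, 0.3)
  z[2, 2, ] <- c(0.2, 1.2)
  z[3, 2, ] <- c(0.5, 0.5)
  ch <- decide(z, seed = 4)
  expect_equal(ch[1:2], c("right", "left"), ignore_attr = TRUE)
  expect_equal(attr(ch, "ties"), c(FALSE, FALSE, TRUE))
  expect_true(ch[3] %in% c("right", "left"))
})

test_that("short training reduces the loss and preserves constraints", {
  p <- rnn_init(N = 10, seed = 6)
  res <- rnn_train(p, rnn_train_config(n_trials = 144, max_epochs = 8,
                                       seed = 6), task = tiny_task())
  expect_lt(tail(res$loss_trace, 1), res$loss_trace[1])
  q <- res$params
  expect_true(all(q$W_rec[, q$dale_sign > 0] >= 0))
  expect_true(all(q$W_rec[, q$dale_sign < 0] <= 0))
  expect_true(all(q$W_in >= 0) && all(q$W_out >= 0))
})

test_that("a symmetric zero readout yields chance-level psychometrics", {
  p <- rnn_init(N = 10, seed = 13)
  p$W_out[] <- 0
  tab <- psychometric(p, n_per_condition = 3, seed = 3, task = tiny_task())
  expect_equal(nrow(tab), 72)
  expect_equal(mean(tab$frac_right), 0.5, tolerance = 0.15)
})
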