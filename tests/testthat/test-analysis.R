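test_that("axis projections contrast node pairs and respect antisymmetry", {
  N <- 12
  Q <- qr.Q(qr(withr::with_seed(3, matrix(rnorm(N * N), N))))[, 1:8]
  axes <- axis_set(Q)
  expect_named(axes, c("context", "choice", "motion", "color"))
  for (a in axes) expect_equal(sum(a^2), 1, tolerance = 1e-12)
  # responses with equal loading on both nodes of a pair project to zero
  conds <- ctx_dm_conditions()[1:2, ]
  K <- 2; Tn <- 4
  xl <- array(0, c(K, Tn, 8))
  xl[, , 3] <- 1; xl[, , 4] <- 1   # equal on both motion nodes
  y <- array(tcrossprod(matrix(xl, K * Tn, 8), Q), c(K, Tn, N))
  pr <- project_onto_axes(y, axes["motion"], conds)
  expect_equal(pr$mean, rep(0, nrow(pr)), tolerance = 1e-12)
})

test_that("planted suppression shows in the axis variance ratio", {
  # synthetic population in which the irrelevant stream is gated off; the
  # grid must be fine enough for the context memory to engage
  conds <- ctx_dm_conditions()
  task <- ctx_dm_task(dt_ms = 100)
  # alpha matched to the grid (dt/tau with tau = 200 ms) so the context
  # memory operates on the intended real-time scale
  batch <- make_batch(conds, 4, seed = 3, task = task, sigma_in = 0,
                      alpha = 0.5)
  x <- simulate_latent(example_suppression_circuit(sigma_rec = 0,
                                                   alpha = 0.5),
                       batch, sigma_rec = 0)
  N <- 16
  Q0 <- qr.Q(qr(withr::with_seed(5, matrix(rnorm(N * N), N))))[, 1:8]
  y <- array(tcrossprod(matrix(x, prod(dim(x)[1:2]), 8), Q0),
             c(dim(x)[1:2], N))
  axes <- axis_set(Q0)
  sup <- suppression_ratio(y, batch$conditions, axes$motion, "motion",
                           which(task$stim_steps))
  expect_lt(sup$ratio, 0.5)
})

test_that("the linear decoder is exact on noiseless linear data", {
  set.seed(8)
  N <- 10
  conds <- ctx_dm_conditions()
  idx <- rep(seq_len(nrow(conds)), 2)
  v <- rnorm(N)
  Tn <- 6
  y <- array(0, c(length(idx), Tn, N))
  for (k in seq_along(idx)) {
    y[k, , ] <- outer(rep(conds$motion_coherence[idx[k]], Tn), v)
  }
  dec <- train_decoder(y, conds[idx, ], stim_steps = 1:Tn, seed = 2)
  expect_equal(dec$r2_train, 1, tolerance = 1e-9)
  expect_equal(dec$r2_test, 1, tolerance = 1e-9)
  # the axis spans the same direction as the generating vector
  expect_equal(abs(sum(dec$axis * v / sqrt(sum(v^2)))), 1, tolerance = 1e-6)
  expect_error(train_decoder(y, within(conds[idx, ],
                                       motion_coherence <- 0.2),
                             1:Tn), "coherence")
})

test_that("solution clustering recovers planted families", {
  set.seed(12)
  centers <- list(matrix(rnorm(64, 0), 8), matrix(rnorm(64, 3), 8),
                  matrix(rnorm(64, -3), 8))
  ws <- list(); truth <- integer(0)
  for (g in 1:3) for (i in 1:12) {
    ws[[length(ws) + 1L]] <- centers[[g]] + matrix(rnorm(64, sd = 0.1), 8)
    truth <- c(truth, g)
  }
  sol <- cluster_solutions(ws, n_components = 3, seed = 7)
  expect_length(sol$labels, length(ws))
  tab <- table(sol$labels, truth)
  # perfect recovery up to label permutation
  expect_equal(sum(apply(tab, 1, max)), length(ws))
  expect_true(all(sol$within_cor > 0.9))
  # identical inputs collapse to one degenerate cluster
  same <- replicate(5, centers[[1]], simplify = FALSE)
  expect_equal(unique(cluster_solutions(same, 3)$labels), 1L)
  expect_error(cluster_solutions(ws[1:2], 3), "components")
})

test_that("uniqueness statistics behave at the identical and null extremes", {
  w <- matrix(rnorm(64), 8)
  same <- uniqueness(list(w, w, w))
  expect_equal(same$mean, 1, tolerance = 1e-12)
  set.seed(5)
  rand <- uniqueness(replicate(60, matrix(rnorm(64), 8), simplify = FALSE))
  expect_lt(abs(rand$mean), 0.1)
  expect_error(uniqueness(list(w)), "two fits")
})

test_that("the variance ratio separates within- from across-network spread", {
  set.seed(6)
  jitter_fits <- function(center, k, sd) {
    lapply(seq_len(k), function(i) center + matrix(rnorm(64, sd = sd), 8))
  }
  # all networks share one solution: ratio near 1
  c0 <- matrix(rnorm(64), 8)
  same <- variance_ratio(lapply(1:6, function(i) jitter_fits(c0, 4, 0.2)))
  expect_equal(same$ratio, 1, tolerance = 0.5)
  # two well-separated solution families: ratio far above 1
  c1 <- matrix(rnorm(64, 2), 8)
  two <- variance_ratio(lapply(1:6, function(i) {
    jitter_fits(if (i %% 2) c0 else c1, 4, 0.05)
  }))
  expect_gt(two$ratio, 10)
  expect_error(variance_ratio(list(jitter_fits(c0, 3, 0.1))), "two networks")
})

test_that("principal-component variance capture matches a direct spectrum", {
  set.seed(10)
  K <- 30; Tn <- 5; N <- 12
  y <- array(rnorm(K * Tn * N), c(K, Tn, N))
  got <- pc_variance_captured(y, 4)
  M <- matrix(y, K * Tn, N)
  ev <- eigen(cov(M), only.values = TRUE)$values
  expect_equal(got, 100 * sum(ev[1:4]) / sum(ev), tolerance = 1e-8)
})
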