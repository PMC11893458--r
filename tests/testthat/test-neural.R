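# helper: long-form spike-count table generated from per-unit rate profiles
make_counts <- function(n_cond = 8, n_units = 6, n_trials = 6, n_bins = 15,
                        seed = 1) {
  withr::with_seed(seed, {
    profiles <- array(runif(n_cond * n_bins * n_units, 0, 10),
                      c(n_cond, n_bins, n_units))
    profiles[, , n_units] <- 5            # constant-rate unit: dropped
    rows <- expand.grid(unit = seq_len(n_units),
                        bin = seq_len(n_bins),
                        trial_in_cond = seq_len(n_trials),
                        condition = seq_len(n_cond))
    rows$trial <- (rows$condition - 1L) * n_trials + rows$trial_in_cond
    lam <- profiles[cbind(rows$condition, rows$bin, rows$unit)] * 0.05
    rows$count <- rpois(nrow(rows), lam)
    rows
  })
}

test_that("rate preprocessing centers, denoises and drops degenerate units", {
  conds <- ctx_dm_conditions()[1:8, ]
  counts <- make_counts()
  pop <- suppressWarnings(
    preprocess_rates(counts, conds, var_frac = 0.5, min_trials = 4))
  expect_s3_class(pop, "rate_population")
  # cross-condition mean is zero at every timestep (both splits)
  for (arr in list(pop$rates, pop$rates_test)) {
    expect_lt(max(abs(colMeans(arr))), 1e-10)
  }
  # retained components match a brute-force cumulative-variance count
  # (centering is exact, so PCA reduces to the covariance spectrum)
  expect_true(pop$pca$cum_var >= 0.5)
  expect_true(dim(pop$rates)[3] == pop$pca$n_components)
  # conditions below the trial minimum are dropped with a warning
  thin <- counts[!(counts$condition == 1 &
                     counts$trial_in_cond > 2), ]
  expect_warning(preprocess_rates(thin, conds, min_trials = 4), "fewer than")
})

test_that("the synthetic population respects its variance bookkeeping", {
  truth <- example_suppression_circuit()
  gen <- generate_synthetic_population(truth, N_units = 24,
                                       task_variance_fraction = 0.1,
                                       noise_sd = 0, seed = 3)
  y <- gen$pop$rates
  # variance in the embedded task subspace ~ requested fraction
  M <- matrix(y, prod(dim(y)[1:2]), dim(y)[3])
  proj <- M %*% gen$truth$embedding
  frac <- sum(proj^2) / sum(M^2)
  expect_equal(frac, 0.1, tolerance = 0.02)
  expect_error(
    generate_synthetic_population(truth, 24, task_variance_fraction = 0),
    "task_variance_fraction")
  expect_error(generate_synthetic_population(truth, 4), "N_units")
})

test_that("the neural-data loss reduces to its limits", {
  truth <- example_suppression_circuit()
  gen <- generate_synthetic_population(truth, N_units = 16,
                                       task_variance_fraction = 0.5,
                                       noise_sd = 0.02, seed = 5)
  cfg <- latent_fit_config(seed = 1, max_epochs = 2)
  ns <- asNamespace("latentcircuit")
  batch <- make_batch(gen$pop$conditions, 1L, seed = 1,
                      task = gen$pop$task, sigma_in = 0,
                      alpha = gen$pop$alpha)
  lc <- ns$latent_init(16, 8, seed = 2, alpha = 0.2, sigma_rec = 0,
                       intercept = TRUE)
  theta <- list(B = lc$B_cayley, w_rec = lc$w_rec, w_in = lc$w_in,
                w_out = lc$w_out, b = matrix(lc$b, ncol = 1))
  cfg0 <- cfg; cfg0$lambda <- 0
  gl0 <- ns$neural_loss_grad(theta, lc, gen$pop, batch, cfg0)
  gl1 <- ns$neural_loss_grad(theta, lc, gen$pop, batch, cfg)
  # lambda = 0 drops exactly the subspace term
  expect_equal(gl1$loss - gl0$loss, 0.5 * gl1$terms[["r_q2"]],
               tolerance = 1e-10)
  expect_equal(gl0$terms[["r_x2"]], gl1$terms[["r_x2"]])
})

test_that("neural-data gradients match finite differences", {
  truth <- example_suppression_circuit()
  gen <- generate_synthetic_population(truth, N_units = 10,
                                       task_variance_fraction = 0.5,
                                       noise_sd = 0.05, seed = 6,
                                       task = ctx_dm_task_pfc(n_observed = 5),
                                       conditions = ctx_dm_conditions()[seq(1, 72, by = 12), ])
  ns <- asNamespace("latentcircuit")
  pop <- gen$pop
  batch <- make_batch(pop$conditions, 1L, seed = 1, task = pop$task,
                      sigma_in = 0, alpha = pop$alpha)
  lc <- ns$latent_init(10, 8, seed = 4, alpha = 0.2, sigma_rec = 0,
                       intercept = TRUE)
  theta <- list(B = lc$B_cayley,
                w_rec = lc$w_rec,
                w_in = matrix(abs(rnorm(48, 0.5, 0.1)), 8, 6),
                w_out = matrix(abs(rnorm(16, 0.5, 0.1)), 2, 8),
                b = matrix(rnorm(10, sd = 0.1), ncol = 1))
  cfg <- latent_fit_config(seed = 1, lambda = 0.7, sigma_rec = 0)
  f <- function(th) ns$neural_loss_grad(th, lc, pop, batch, cfg)$loss
  gl <- ns$neural_loss_grad(theta, lc, pop, batch, cfg)
  eps <- 1e-6
  for (nm in names(theta)) {
    gnum <- theta[[nm]] * 0
    for (i in seq_along(gnum)) {
      tp <- theta; tp[[nm]][i] <- tp[[nm]][i] + eps
      tm <- theta; tm[[nm]][i] <- tm[[nm]][i] - eps
      gnum[i] <- (f(tp) - f(tm)) / (2 * eps)
    }
    expect_lt(max(abs(gnum - gl$grads[[nm]])) / (max(abs(gnum)) + 1e-12),
              1e-4)
  }
})

test_that("fitting a planted population recovers the suppression signs", {
  truth <- example_suppression_circuit()
  gen <- generate_synthetic_population(truth, N_units = 20,
                                       task_variance_fraction = 0.5,
                                       noise_sd = 0.02, seed = 11)
  fits <- lapply(1:3, function(i) {
    fit_neural(gen$pop, latent_fit_config(seed = 40 + i, lambda = 0.5,
                                          max_epochs = 400))
  })
  best <- fits[[which.max(vapply(fits, function(f) f$metrics$r2_total,
                                 numeric(1)))]]
  w <- best$circuit$w_rec
  # context -> irrelevant-sensory inhibition: negative in >= 3 of 4, plus
  # sensory -> choice excitation: positive in >= 3 of 4
  key_inhib <- c(w[5, 1], w[6, 1], w[3, 2], w[4, 2])
  key_excit <- c(w[7, 4], w[7, 6], w[8, 3], w[8, 5])
  expect_gte(sum(key_inhib < 0), 3)
  expect_gte(sum(key_excit > 0), 3)
  # the fit reproduces the held-out responses well in the task subspace
  expect_lt(best$metrics$r_x2, 0.5)
})

test_that("an intercept absorbs constant responses", {
  conds <- ctx_dm_conditions()
  task <- ctx_dm_task_pfc()
  K <- nrow(conds); To <- length(task$observed_steps); N <- 12
  const <- withr::with_seed(8, rnorm(N))
  y <- aperm(array(const, c(N, K, To)), c(2, 3, 1))
  pop <- rate_population(y, y, conds, task = task)
  fit <- fit_neural(pop, latent_fit_config(seed = 2, max_epochs = 150))
  x <- simulate_latent(fit$circuit, make_batch(conds, 1, seed = 1,
                                               task = task, sigma_in = 0),
                       seed = 1, sigma_rec = 0)
  # latent contribution to the data window is negligible next to b
  xo <- x[, task$observed_steps, , drop = FALSE]
  contrib <- fit$circuit$Q %*% t(matrix(xo, prod(dim(xo)[1:2]), 8))
  expect_lt(mean(abs(sweep(contrib + fit$circuit$b, 1, const, "-"))), 0.2)
})
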