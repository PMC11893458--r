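# Shared fixtures. Heavy artifacts (a trained 50-unit network and a latent
# circuit ensemble fitted to it) are built once per test run and cached in
# this environment; the scientific acceptance checks all interrogate the
# same trained network, as one study would.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# short task grid (10 steps) for cheap dynamical tests
tiny_task <- function() ctx_dm_task(dt_ms = 300, trial_ms = 3000)

# small batch on the tiny grid
tiny_batch <- function(n_per = 1L, seed = 5L, sigma_in = 0.01) {
  make_batch(ctx_dm_conditions(), n_per, seed = seed, task = tiny_task(),
             sigma_in = sigma_in)
}

# single-unit network for hand-computed update checks
unit_rnn <- function(w = 0.5, win = 1, alpha = 0.2) {
  structure(list(W_rec = matrix(w), W_in = matrix(win),
                 W_out = matrix(1, 1, 1), dale_sign = 1, N = 1L,
                 tau = 200, dt = 40, alpha = alpha, sigma_rec = 0),
            class = "rnn_params")
}

# the study-condition trained network (standard hyperparameters), shared
# across the acceptance checks
trained_rnn <- function() {
  fixture("trained_rnn", function() {
    p <- rnn_init(N = 50, seed = 2024)
    rnn_train(p, rnn_train_config(seed = 2024, max_epochs = 800))
  })
}

# responses of the trained network on a fresh condition-balanced batch
trained_responses <- function() {
  fixture("trained_responses", function() {
    p <- trained_rnn()$params
    batch <- make_batch(ctx_dm_conditions(), 8L, seed = 4242,
                        alpha = p$alpha)
    sim <- rnn_simulate(p, batch, seed = 4243)
    list(batch = batch, y = sim$y, z = sim$z)
  })
}

# ensemble of latent circuits fitted to the trained network (20 random
# initializations, each run to a deep stopping criterion; the best 10 by
# held-out fit quality are kept)
trained_ensemble <- function() {
  fixture("trained_ensemble", function() {
    tr <- trained_responses()
    fit_ensemble(tr$y, tr$z, tr$batch, n_inits = 20L, top_k = 10L,
                 latent_fit_config(seed = 91, max_epochs = 2500,
                                   patience = 100, tol = 1e-4))
  })
}

# two additional independently trained networks (shared by the
# task-performance and across-network variability checks)
extra_rnn_params <- function() {
  fixture("extra_rnn_params", function() {
    lapply(2:3, function(k) {
      p <- rnn_init(N = 50, seed = 2024 + 7L * k)
      rnn_train(p, rnn_train_config(seed = 2024 + 7L * k,
                                    max_epochs = 800))$params
    })
  })
}

# plain-R readout used when constructing synthetic data in tests
apply_readout_for_test <- function(W_out, y) {
  d <- dim(y)
  z <- array(0, c(d[1], d[2], nrow(W_out)))
  for (k in seq_len(d[1])) for (t in seq_len(d[2])) {
    z[k, t, ] <- W_out %*% y[k, t, ]
  }
  z
}
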