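#' Condition-averaged rate population container
#'
#' Holds condition-averaged firing-rate responses ready for latent circuit
#' fitting: two disjoint trial splits averaged separately (`rates` for
#' fitting, `rates_test` for validation), the condition table, and the
#' indices of the model timesteps at which responses were observed.
#'
#' @param rates,rates_test arrays, conditions x observed timesteps x units
#' @param conditions condition table matching the first dimension
#' @param task the `ctx_dm_task` time grid the data are aligned to
#' @param observed_steps indices into the task grid covered by the data
#' @param alpha Euler step ratio used when fitting dynamics to these data
#' @return object of class `rate_population`
#' @export
rate_population <- function(rates, rates_test, conditions,
                            task = ctx_dm_task_pfc(),
                            observed_steps = task$observed_steps,
                            alpha = 0.2) {
  stopifnot(dim(rates)[1] == nrow(conditions),
            dim(rates)[2] == length(observed_steps))
  structure(list(rates = rates, rates_test = rates_test,
                 conditions = conditions, task = task,
                 observed_steps = observed_steps, alpha = alpha),
            class = "rate_population")
}

#' @export
print.rate_population <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("rate_population: %d conditions x %d timesteps x %d units\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Preprocess spike counts into condition-averaged rate responses
#'
#' Takes a long-form table of binned spike counts (one row per unit, trial
#' and time bin) and produces a [rate_population()]: trials are split into
#' two disjoint halves within each condition; within each split, responses
#' are trial-averaged per condition, z-scored per unit, smoothed with a
#' Gaussian kernel, centered by subtracting the cross-condition mean at
#' each timestep, and denoised by projecting onto the leading principal
#' components that explain the requested fraction of total variance
#' (computed on the fitting split and applied to both). Units in the output
#' are principal-component scores.
#'
#' @param counts data frame with columns `unit`, `trial`, `condition`
#'   (index into `conditions`), `bin` (1-based time bin) and `count`
#' @param conditions condition table
#' @param bin_ms time bin width, ms
#' @param smooth_sd_ms Gaussian smoothing kernel sd, ms
#' @param var_frac cumulative variance fraction retained by the denoising
#'   projection
#' @param min_trials conditions require at least this many trials in total;
#'   conditions below it are dropped with a warning
#' @param task,alpha forwarded to [rate_population()]
#' @param seed seed for the trial split
#' @return a [rate_population()] whose `pca` element records the rotation,
#'   number of components and explained variance
#' @export
preprocess_rates <- function(counts, conditions, bin_ms = 50,
                             smooth_sd_ms = 40, var_frac = 0.5,
                             min_trials = 4L, task = ctx_dm_task_pfc(),
                             alpha = 0.2, seed = 1L) {
  units <- sort(unique(counts$unit))
  bins <- sort(unique(counts$bin))
  n_cond <- nrow(conditions)
  keep <- vapply(seq_len(n_cond), function(ci) {
    length(unique(counts$trial[counts$condition == ci])) >= min_trials
  }, logical(1))
  if (!all(keep)) {
    warning(sprintf("dropping %d condition(s) with fewer than %d trials",
                    sum(!keep), min_trials))
  }
  cond_idx <- which(keep)
  avg_split <- function(split_sel) {
    arr <- array(NA_real_, c(length(cond_idx), length(bins), length(units)))
    for (ci in seq_along(cond_idx)) {
      sub <- counts[counts$condition == cond_idx[ci] & split_sel, ]
      m <- tapply(sub$count, list(match(sub$bin, bins), match(sub$unit, units)),
                  mean)
      arr[ci, , ] <- m / (bin_ms / 1000)   # counts -> spikes/s
    }
    arr
  }
  # split trials in half within condition
  trial_tab <- unique(counts[c("trial", "condition")])
  in_train <- with_seed_or_not(seed, {
    sel <- logical(max(trial_tab$trial))
    for (ci in cond_idx) {
      tr <- sample(trial_tab$trial[trial_tab$condition == ci])
      sel[tr[seq_len(ceiling(length(tr) / 2))]] <- TRUE
    }
    sel
  })
  raw_tr <- avg_split(in_train[counts$trial])
  raw_te <- avg_split(!in_train[counts$trial])
  norm_split <- function(arr) {
    # z-score per unit over conditions and time
    for (u in seq_len(dim(arr)[3])) {
      v <- arr[, , u]
      s <- sd(v)
      arr[, , u] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
    }
    arr <- gauss_smooth(arr, smooth_sd_ms / bin_ms)
    # condition-independent term: mean across conditions at each timestep
    sweep(arr, c(2, 3), colMeans(arr), "-")
  }
  tr <- norm_split(raw_tr)
  te <- norm_split(raw_te)
  # drop all-zero units (constant before z-scoring)
  live <- apply(tr, 3, function(v) any(v != 0))
  tr <- tr[, , live, drop = FALSE]
  te <- te[, , live, drop = FALSE]
  # denoise: PCA on pooled (condition,time) x unit matrix of the fit split
  M <- matrix(tr, prod(dim(tr)[1:2]), dim(tr)[3])
  pc <- prcomp(M, center = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_comp <- which(cum >= var_frac)[1]
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  project <- function(arr) {
    P <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3]) %*% rot
    array(P, c(dim(arr)[1:2], n_comp))
  }
  pop <- rate_population(project(tr), project(te),
                         conditions[cond_idx, , drop = FALSE],
                         task = task, alpha = alpha)
  pop$pca <- list(rotation = rot, n_components = n_comp,
                  cum_var = cum[n_comp], units_kept = which(live))
  pop
}

# Gaussian smoothing along the time dimension of a [cond, time, unit] array
gauss_smooth <- function(arr, sd_bins) {
  if (sd_bins <= 0) return(arr)
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- dnorm(seq(-half, half), sd = sd_bins)
  Tn <- dim(arr)[2]
  out <- arr
  for (t in seq_len(Tn)) {
    lo <- max(1L, t - half); hi <- min(Tn, t + half)
    w <- kern[(lo:hi) - t + half + 1L]
    w <- w / sum(w)
    sl <- arr[, lo:hi, , drop = FALSE]
    out[, t, ] <- apply(sweep(sl, 2, w, "*"), c(1, 3), sum)
  }
  out
}

#' Handcrafted suppression-mechanism circuit
#'
#' An 8-node circuit implementing context-dependent decision-making through
#' inhibition of the irrelevant sensory pathway: the motion-context node
#' inhibits the color-sensory nodes and vice versa, sensory nodes excite
#' their associated choice nodes, and the choice nodes compete via mutual
#' inhibition. The context nodes carry slow self-excitation and
#' winner-take-all competition, so the cued context stays active (and keeps
#' suppressing the irrelevant stream) after the cue turns off. With the
#' default weights the circuit performs the task perfectly on noiseless
#' trials. Used as ground truth for synthetic surrogate populations and
#' recovery tests.
#'
#' Node order: motion context, color context, motion-left, motion-right,
#' color-green, color-red, right choice, left choice.
#'
#' @param ctx_inhibition strength of the context-to-irrelevant-sensory
#'   inhibition (positive number; entered with negative sign)
#' @param alpha,sigma_rec dynamics constants
#' @return a [latent_circuit()] with `N = n = 8` and identity embedding
#' @export
example_suppression_circuit <- function(ctx_inhibition = 2,
                                        alpha = 0.2, sigma_rec = 0.15) {
  n <- 8L
  w <- matrix(0, n, n)
  w[1, 1] <- 0.9; w[2, 2] <- 0.9        # slow context memory
  w[1, 2] <- -0.5; w[2, 1] <- -0.5      # context winner-take-all
  w[5:6, 1] <- -ctx_inhibition          # motion context inhibits color
  w[3:4, 2] <- -ctx_inhibition          # color context inhibits motion
  w[cbind(3:6, 3:6)] <- 0.4             # sensory self-excitation
  w[7, 4] <- 1; w[7, 6] <- 1            # right motion / red -> right choice
  w[8, 3] <- 1; w[8, 5] <- 1            # left motion / green -> left choice
  w[cbind(7:8, 7:8)] <- 0.3             # choice integration
  w[7, 8] <- -0.6; w[8, 7] <- -0.6      # choice competition
  w_in <- matrix(0, n, 6)
  w_in[cbind(1:6, 1:6)] <- c(0.15, 0.15, 1, 1, 1, 1)
  w_out <- matrix(0, 2, n)
  w_out[1, 7] <- 1; w_out[2, 8] <- 1
  latent_circuit(w, w_in, w_out, matrix(0, n, n),
                 alpha = alpha, sigma_rec = sigma_rec)
}

#' Generate a synthetic surrogate rate population with known ground truth
#'
#' Simulates a ground-truth latent circuit over all task conditions, embeds
#' the trajectories into `N_units` dimensions through a random orthonormal
#' map, mixes in task-irrelevant smooth components so that the task
#' subspace occupies a set fraction of total variance, adds independent
#' observation noise to two disjoint splits (emulating finite-trial
#' averages), and centers each split across conditions. The result mimics
#' the statistical structure of preprocessed cortical recordings --
#' condition structure, low task-relevant variance, additive noise -- while
#' the generating circuit and embedding are known exactly.
#'
#' @param ground_truth generating [latent_circuit()] (e.g.
#'   [example_suppression_circuit()])
#' @param N_units ambient dimension of the surrogate population
#' @param task_variance_fraction fraction of total variance occupied by the
#'   embedded task subspace, in (0, 1]
#' @param noise_sd observation noise sd added to each split
#' @param seed integer seed
#' @param task task grid (defaults to the firing-rate-data variant)
#' @param conditions condition table
#' @return list with the [rate_population()] (`pop`) and a `truth` record
#'   (circuit, embedding, scales)
#' @export
generate_synthetic_population <- function(ground_truth, N_units = 40L,
                                          task_variance_fraction = 0.2,
                                          noise_sd = 0.05, seed = 1L,
                                          task = ctx_dm_task_pfc(),
                                          conditions = ctx_dm_conditions()) {
  if (task_variance_fraction <= 0 || task_variance_fraction > 1) {
    stop("task_variance_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- ground_truth$n
  if (N_units < n) stop("N_units must be >= the circuit size", call. = FALSE)
  batch <- make_batch(conditions, 1L, seed = seed, task = task,
                      sigma_in = 0, alpha = ground_truth$alpha)
  x <- simulate_latent(ground_truth, batch, seed = seed, sigma_rec = 0)
  obs <- task$observed_steps
  xo <- x[, obs, , drop = FALSE]
  K <- dim(xo)[1]; To <- dim(xo)[2]
  with_seed_or_not(seed + 1L, {
    E <- qr.Q(qr(matrix(rnorm(N_units * N_units), N_units)))
    E_task <- E[, seq_len(n), drop = FALSE]
    E_null <- E[, -seq_len(n), drop = FALSE]
    Xc <- sweep(xo, c(2, 3), apply(xo, c(2, 3), mean), "-")
    task_sig <- array(tcrossprod(matrix(Xc, K * To, n), E_task),
                      c(K, To, N_units))
    v_task <- mean(task_sig^2)
    if (task_variance_fraction < 1) {
      # smooth task-irrelevant trajectories per condition
      irr <- array(rnorm(K * To * (N_units - n)), c(K, To, N_units - n))
      irr <- gauss_smooth(irr, 2)
      irr <- sweep(irr, c(2, 3), apply(irr, c(2, 3), mean), "-")
      irr_sig <- array(tcrossprod(matrix(irr, K * To, N_units - n), E_null),
                       c(K, To, N_units))
      s <- sqrt(v_task * (1 - task_variance_fraction) /
                  (task_variance_fraction * mean(irr_sig^2)))
      base <- task_sig + s * irr_sig
    } else {
      base <- task_sig
    }
    splits <- lapply(1:2, function(i) {
      y <- base + array(rnorm(length(base), sd = noise_sd), dim(base))
      sweep(y, c(2, 3), apply(y, c(2, 3), mean), "-")
    })
  })
  pop <- rate_population(splits[[1]], splits[[2]], conditions, task = task,
                         alpha = ground_truth$alpha)
  list(pop = pop,
       truth = list(circuit = ground_truth, embedding = E_task,
                    task_variance_fraction = task_variance_fraction,
                    noise_sd = noise_sd, seed = seed))
}
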