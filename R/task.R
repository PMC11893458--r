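#' Context-dependent decision-making task definition
#'
#' Constructs the timing and amplitude parameters of the context-dependent
#' decision-making task. Each trial presents a context cue (motion or color),
#' then after a delay a compound sensory stimulus with a motion and a color
#' evidence stream. The network must report the sign of the relevant
#' coherence on two output channels. Six input channels carry, in order, the
#' motion-context cue, the color-context cue, motion-left, motion-right,
#' color-green and color-red evidence.
#'
#' Time is discretized on a uniform grid of `dt_ms` steps; step `i` covers
#' `[(i-1)*dt_ms, i*dt_ms)` and carries the input at its left edge. Epoch
#' boundaries snap to the nearest grid point. With the defaults the trial
#' lasts 3,000 ms (75 steps of 40 ms): the cue is shown 320--1,000 ms, the
#' stimulus starts at 1,200 ms, and targets switch on 2,250 ms into the
#' trial, covering the final 750 ms response window.
#'
#' The squared output error is penalized only while the context cue is shown
#' (where the network must stay at baseline) and during the response window;
#' `mask_cue = FALSE` drops the cue epoch from the penalty (used for the
#' firing-rate-data task variant, see [ctx_dm_task_pfc()]).
#'
#' @param dt_ms timestep in ms
#' @param trial_ms trial duration in ms
#' @param cue_on_ms,cue_off_ms context-cue epoch
#' @param stim_on_ms sensory stimulus onset (stimulus stays on to trial end)
#' @param target_on_ms time from which choice targets are enforced
#' @param response_ms duration of the penalized response window at trial end
#' @param cue_hi,cue_lo cue drive on the cued / uncued context channel
#' @param baseline baseline drive `u_0` added to every channel at every step
#' @param target_hi,target_lo target output levels for chosen / unchosen side
#' @param sigma_in input noise magnitude
#' @param mask_cue whether the cue epoch contributes to the output penalty
#' @return an object of class `ctx_dm_task`
#' @export
ctx_dm_task <- function(dt_ms = 40, trial_ms = 3000,
                        cue_on_ms = 320, cue_off_ms = 1000,
                        stim_on_ms = 1200, target_on_ms = 2250,
                        response_ms = 750,
                        cue_hi = 1.2, cue_lo = 0.2, baseline = 0.2,
                        target_hi = 1.2, target_lo = 0.2,
                        sigma_in = 0.01, mask_cue = TRUE) {
  n_steps <- as.integer(round(trial_ms / dt_ms))
  snap <- function(x) round(x / dt_ms) * dt_ms
  t_ms <- (seq_len(n_steps) - 1L) * dt_ms
  cue_steps <- t_ms >= snap(cue_on_ms) & t_ms < snap(cue_off_ms)
  stim_steps <- t_ms >= snap(stim_on_ms)
  target_steps <- t_ms >= snap(target_on_ms)
  resp_steps <- t_ms >= snap(trial_ms - response_ms)
  mask <- resp_steps
  if (mask_cue) mask <- mask | cue_steps
  structure(list(
    dt_ms = dt_ms, trial_ms = trial_ms, n_steps = n_steps, t_ms = t_ms,
    cue_steps = cue_steps, stim_steps = stim_steps,
    target_steps = target_steps, mask = mask,
    cue_hi = cue_hi, cue_lo = cue_lo, baseline = baseline,
    target_hi = target_hi, target_lo = target_lo, sigma_in = sigma_in,
    channels = c("u_m", "u_c", "u_mL", "u_mR", "u_cG", "u_cR")
  ), class = "ctx_dm_task")
}

#' Task variant matching condition-averaged firing-rate recordings
#'
#' A 1,500-ms trial on a 10-ms grid (150 steps): contextual input for the
#' whole trial, sensory stimulus from 750 ms, targets and output penalty in
#' the final 250 ms only. The last `n_observed` steps are the window in
#' which recorded responses are available and fitted.
#'
#' @param n_observed number of trailing steps with observed responses
#' @param ... overrides passed to [ctx_dm_task()]
#' @return a `ctx_dm_task` with an `observed_steps` index vector
#' @export
ctx_dm_task_pfc <- function(n_observed = 15, ...) {
  task <- ctx_dm_task(dt_ms = 10, trial_ms = 1500, cue_on_ms = 0,
                      cue_off_ms = 1500, stim_on_ms = 750,
                      target_on_ms = 1250, response_ms = 250,
                      mask_cue = FALSE, ...)
  task$observed_steps <- (task$n_steps - n_observed + 1L):task$n_steps
  task
}

#' Enumerate the task's stimulus conditions
#'
#' All combinations of 2 contexts and the signed motion and color coherence
#' levels (72 conditions with the default 6-level grid). The correct choice
#' is `"right"` when the context-relevant coherence is positive.
#'
#' @param coherences signed coherence levels
#' @return data frame with columns `context`, `motion_coherence`,
#'   `color_coherence`, `correct_choice`
#' @export
ctx_dm_conditions <- function(coherences = c(-0.2, -0.12, -0.04, 0.04, 0.12, 0.2)) {
  grid <- expand.grid(context = c("motion", "color"),
                      motion_coherence = coherences,
                      color_coherence = coherences,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rel <- ifelse(grid$context == "motion", grid$motion_coherence,
                grid$color_coherence)
  grid$correct_choice <- ifelse(rel > 0, "right", "left")
  grid[order(grid$context, grid$motion_coherence, grid$color_coherence), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}

#' Noiseless input time series for one condition
#'
#' Context channels carry `cue_hi` (cued context) and `cue_lo` during the
#' cue epoch. From stimulus onset the evidence channels carry
#' `(1 - c)/2` and `(1 + c)/2` for coherence `c`, so that positive coherence
#' favors the right choice. The baseline `u_0` is added to all six channels
#' at every step.
#'
#' @param condition one-row data frame as returned by [ctx_dm_conditions()]
#' @param task a [ctx_dm_task()]
#' @return `n_steps x 6` matrix with named channel columns
#' @export
stimulus_profile <- function(condition, task = ctx_dm_task()) {
  u <- matrix(0, task$n_steps, 6L, dimnames = list(NULL, task$channels))
  cued_motion <- condition$context == "motion"
  u[task$cue_steps, "u_m"] <- if (cued_motion) task$cue_hi else task$cue_lo
  u[task$cue_steps, "u_c"] <- if (cued_motion) task$cue_lo else task$cue_hi
  mc <- condition$motion_coherence; cc <- condition$color_coherence
  u[task$stim_steps, "u_mL"] <- (1 - mc) / 2
  u[task$stim_steps, "u_mR"] <- (1 + mc) / 2
  u[task$stim_steps, "u_cG"] <- (1 - cc) / 2
  u[task$stim_steps, "u_cR"] <- (1 + cc) / 2
  u + task$baseline
}

#' Target outputs and loss mask for one condition
#'
#' Both outputs must stay at `target_lo` outside the response window; from
#' `target_on_ms` the chosen side's target is `target_hi`. Output 1 is the
#' right choice, output 2 the left choice. The mask marks the steps on which
#' the output error is penalized.
#'
#' @inheritParams stimulus_profile
#' @return list with `z_target` (`n_steps x 2`) and logical `mask`
#' @export
target_profile <- function(condition, task = ctx_dm_task()) {
  z <- matrix(task$target_lo, task$n_steps, 2L,
              dimnames = list(NULL, c("z_right", "z_left")))
  hi_col <- if (condition$correct_choice == "right") 1L else 2L
  z[task$target_steps, hi_col] <- task$target_hi
  list(z_target = z, mask = task$mask)
}

#' Generate a batch of task trials
#'
#' Replicates each condition `n_per_condition` times, assembles the
#' noiseless input profiles and adds independent Gaussian input noise
#' `sqrt(2/alpha) * sigma_in * eta` to every channel and step. Deterministic
#' given `seed`.
#'
#' @param conditions data frame of conditions ([ctx_dm_conditions()])
#' @param n_per_condition trials per condition
#' @param seed integer seed for the input noise
#' @param task a [ctx_dm_task()]
#' @param sigma_in input noise magnitude; defaults to the task's value
#' @param alpha Euler step ratio dt/tau of the simulated network, entering
#'   the noise scaling
#' @return a `trial_batch`: list with `u` (trials x time x 6), `z_target`
#'   (trials x time x 2), `mask` (trials x time), `conditions`, `dt_ms`,
#'   `alpha`, `seed`
#' @export
make_batch <- function(conditions, n_per_condition = 1L, seed = 1L,
                       task = ctx_dm_task(), sigma_in = task$sigma_in,
                       alpha = 0.2) {
  if (nrow(conditions) == 0L) stop("`conditions` is empty", call. = FALSE)
  stop_if_not_scalar_count(n_per_condition, "n_per_condition")
  idx <- rep(seq_len(nrow(conditions)), each = n_per_condition)
  K <- length(idx); Tn <- task$n_steps
  u <- array(0, c(K, Tn, 6L))
  z <- array(0, c(K, Tn, 2L))
  mask <- matrix(FALSE, K, Tn)
  profiles <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, , drop = FALSE]
    list(u = stimulus_profile(cond, task), tg = target_profile(cond, task))
  })
  for (k in seq_len(K)) {
    pk <- profiles[[idx[k]]]
    u[k, , ] <- pk$u
    z[k, , ] <- pk$tg$z_target
    mask[k, ] <- pk$tg$mask
  }
  if (sigma_in > 0) {
    u <- u + with_seed_or_not(seed,
      array(sqrt(2 / alpha) * sigma_in * rnorm(length(u)), dim(u)))
  }
  structure(list(u = u, z_target = z, mask = mask,
                 conditions = conditions[idx, , drop = FALSE],
                 dt_ms = task$dt_ms, alpha = alpha, task = task,
                 seed = seed),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("trial_batch: %d trials x %d steps (%d ms), 6 inputs\n",
              d[1], d[2], x$dt_ms * d[2]))
  invisible(x)
}
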