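#' Task-variable axes from a fitted embedding
#'
#' Behavioral axes are differences of embedding columns, renormalized to
#' unit length: context = motion-context minus color-context node columns,
#' choice = right minus left, motion = motion-right minus motion-left,
#' color = red minus green. Projections onto each axis correlate with the
#' activity difference of the corresponding latent node pair.
#'
#' @param Q orthonormal `N x n` embedding with the standard node order
#' @return list of unit-norm `N`-vectors: `context`, `choice`, `motion`,
#'   `color`
#' @export
axis_set <- function(Q) {
  ax <- list(context = Q[, 1] - Q[, 2],
             choice = Q[, 7] - Q[, 8],
             motion = Q[, 4] - Q[, 3],
             color = Q[, 6] - Q[, 5])
  lapply(ax, function(a) a / sqrt(sum(a^2)))
}

#' Project responses onto task axes
#'
#' Inner products of single-trial responses with each axis, averaged
#' within condition, with the across-trial standard deviation.
#'
#' @param y responses, trials x time x N
#' @param axes named list of `N`-vectors ([axis_set()]) or a single vector
#' @param conditions per-trial condition table
#' @return data frame: `axis`, condition columns, `time_step`, `mean`, `sd`
#' @export
project_onto_axes <- function(y, axes, conditions) {
  if (!is.list(axes)) axes <- list(axis = axes)
  d <- dim(y)
  key <- interaction(conditions$context, conditions$motion_coherence,
                     conditions$color_coherence, drop = TRUE)
  out <- list()
  for (nm in names(axes)) {
    proj <- matrix(pool_mat(y), nrow = d[3])   # N x (K*T)
    p <- matrix(crossprod(axes[[nm]], proj), d[1], d[2])  # K x T
    for (lev in levels(key)) {
      rows <- which(key == lev)
      cond <- conditions[rows[1], c("context", "motion_coherence",
                                    "color_coherence")]
      out[[length(out) + 1L]] <- data.frame(
        axis = nm, cond, time_step = seq_len(d[2]),
        mean = colMeans(p[rows, , drop = FALSE]),
        sd = apply(p[rows, , drop = FALSE], 2, sd), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Suppression index of a sensory axis
#'
#' Quantifies context-dependent suppression as the ratio of the
#' across-coherence variance of condition-mean axis projections in the
#' context where the stimulus is irrelevant versus relevant, averaged over
#' the stimulus epoch. Values well below 1 indicate suppression of the
#' irrelevant representation; a ratio near 1 indicates equal representation
#' in both contexts.
#'
#' @param y,conditions responses and per-trial conditions
#' @param axis `N`-vector to project on
#' @param coherence_of `"motion"` or `"color"`: which coherence the axis
#'   represents
#' @param stim_steps stimulus-epoch timestep indices
#' @return list with the `ratio` and the per-context variances
#' @export
suppression_ratio <- function(y, conditions, axis,
                              coherence_of = c("motion", "color"),
                              stim_steps) {
  coherence_of <- match.arg(coherence_of)
  coh <- conditions[[paste0(coherence_of, "_coherence")]]
  d <- dim(y)
  p <- matrix(crossprod(axis, matrix(pool_mat(y), nrow = d[3])), d[1], d[2])
  per_ctx_var <- function(ctx) {
    rows <- conditions$context == ctx
    m <- tapply(rowMeans(p[rows, stim_steps, drop = FALSE]), coh[rows], mean)
    var(as.numeric(m))
  }
  relevant <- per_ctx_var(coherence_of)
  irrelevant <- per_ctx_var(setdiff(c("motion", "color"), coherence_of))
  list(ratio = irrelevant / relevant, relevant_var = relevant,
       irrelevant_var = irrelevant)
}

#' Linear decoder of signed motion coherence
#'
#' Least-squares regression of the per-trial signed motion coherence on
#' population activity, pooled over trials and stimulus-epoch timesteps,
#' fitted on a 50/50 trial split and scored (coefficient of determination)
#' on both splits. The normalized coefficient vector defines the decoder
#' axis.
#'
#' @param y responses, trials x time x N
#' @param conditions per-trial condition table
#' @param stim_steps stimulus-epoch timestep indices
#' @param seed seed for the train/test split
#' @return list with `beta`, `intercept`, `axis` (unit norm), `r2_train`,
#'   `r2_test`
#' @export
train_decoder <- function(y, conditions, stim_steps, seed = 1L) {
  coh <- conditions$motion_coherence
  if (length(unique(coh)) < 2) stop("need >= 2 coherence levels", call. = FALSE)
  split <- split_trials(conditions, seed)
  d <- dim(y)
  pool <- function(idx) {
    Y <- t(pool_mat(y[idx, stim_steps, , drop = FALSE]))  # rows: (k,t)
    list(X = Y, c = rep(coh[idx], times = length(stim_steps)))
  }
  tr <- pool(split$train); te <- pool(split$test)
  # minimum-norm least squares (pseudoinverse), robust to rank-deficient
  # response matrices
  X1 <- cbind(1, tr$X)
  sv <- svd(X1)
  pos <- sv$d > max(sv$d) * 1e-10
  coefs <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], tr$c)) / sv$d[pos])
  beta <- coefs[-1]
  b0 <- coefs[1]
  score <- function(p) 1 - sum((p$c - (p$X %*% beta + b0))^2) /
    sum((p$c - mean(p$c))^2)
  list(beta = beta, intercept = b0, axis = beta / sqrt(sum(beta^2)),
       r2_train = score(tr), r2_test = score(te))
}

#' Cluster an ensemble of latent connectivity solutions
#'
#' Flattens the recurrent connectivity matrices of converged fits, projects
#' them onto their leading principal components, and partitions them with
#' a Gaussian mixture model (full covariance, seeded). Returns per-cluster
#' mean connectivity matrices and within-cluster correlations to the mean.
#'
#' @param w_rec_list list of `n x n` matrices
#' @param n_components mixture components
#' @param n_pcs principal components to retain for clustering
#' @param seed seed for the mixture fit
#' @return list with `labels`, `projection` (fits x 2 PC scores),
#'   `var_explained`, `cluster_means` and `within_cor`
#' @export
cluster_solutions <- function(w_rec_list, n_components = 3L, n_pcs = 2L,
                              seed = 1L) {
  if (length(w_rec_list) < n_components) {
    stop("need at least as many fits as mixture components", call. = FALSE)
  }
  M <- do.call(rbind, lapply(w_rec_list, as.numeric))
  pc <- prcomp(M, center = TRUE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  X <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- with_seed_or_not(seed, {
    if (sum(pc$sdev^2) < 1e-12) {
      NULL  # all solutions identical: a single degenerate cluster
    } else {
      Mclust(X, G = n_components, modelNames = "VVV", verbose = FALSE)
    }
  })
  labels <- if (is.null(fit)) rep(1L, nrow(M)) else fit$classification
  n_dim <- sqrt(ncol(M))
  means <- lapply(sort(unique(labels)), function(g) {
    matrix(colMeans(M[labels == g, , drop = FALSE]), n_dim, n_dim)
  })
  within <- vapply(seq_along(w_rec_list), function(i) {
    m <- means[[match(labels[i], sort(unique(labels)))]]
    suppressWarnings(cor(as.numeric(w_rec_list[[i]]), as.numeric(m)))
  }, numeric(1))
  list(labels = labels, projection = X,
       var_explained = cumsum(pc$sdev^2)[n_pcs] / sum(pc$sdev^2),
       cluster_means = means, within_cor = within, mixture = fit)
}

#' Uniqueness of an ensemble's best solution
#'
#' Pearson correlation between the flattened recurrent connectivity of the
#' best fit and each remaining fit. High mean correlation indicates that
#' independent optimization runs converge to one circuit mechanism. The
#' fixed node identities (structural input/output zeros) make weights
#' directly comparable without permutation alignment.
#'
#' @param fits ranked list of `latent_fit` objects (best first) or of
#'   `w_rec` matrices
#' @return list with `mean`, `sd` and the individual `correlations`
#' @export
uniqueness <- function(fits) {
  ws <- lapply(fits, function(f) {
    if (inherits(f, "latent_fit")) f$circuit$w_rec else f
  })
  if (length(ws) < 2) stop("need at least two fits", call. = FALSE)
  best <- as.numeric(ws[[1]])
  cors <- vapply(ws[-1], function(w) {
    w <- as.numeric(w)
    if (sd(w) == 0 || sd(best) == 0) NA_real_ else cor(best, w)
  }, numeric(1))
  list(mean = mean(cors, na.rm = TRUE), sd = sd(cors, na.rm = TRUE),
       correlations = cors)
}

#' Across- versus within-network variability of latent connectivity
#'
#' Ratio of the variance of latent connectivity entries across networks
#' (using each network's best fit) to the average within-network variance
#' across that network's converged fits. Ratios well above 1 mean that the
#' solution found for one network is far more reproducible than the spread
#' of solutions across networks.
#'
#' @param ensembles list (one element per network) of ranked fit lists as
#'   returned by [fit_ensemble()], or lists of `w_rec` matrices
#' @return list with `ratio`, `across_var`, `within_var`
#' @export
variance_ratio <- function(ensembles) {
  if (length(ensembles) < 2) stop("need at least two networks", call. = FALSE)
  mats <- lapply(ensembles, function(fits) {
    do.call(rbind, lapply(fits, function(f) {
      as.numeric(if (inherits(f, "latent_fit")) f$circuit$w_rec else f)
    }))
  })
  best <- do.call(rbind, lapply(mats, function(m) m[1, ]))
  across <- mean(apply(best, 2, var))
  within <- vapply(mats, function(m) {
    if (nrow(m) < 2) return(NA_real_)
    mean(apply(m, 2, var))
  }, numeric(1))
  list(ratio = across / mean(within, na.rm = TRUE), across_var = across,
       within_var = within)
}

#' Permutation test for the dependence of latent connectivity on responses
#'
#' Does the inferred connectivity reflect the neural responses, or only the
#' constraints of the task? Fits `n_fits` circuits to the original data and
#' `n_fits` circuits to data in which responses are permuted across trials
#' (a fresh whole-trial permutation per fit), breaking the link between
#' responses and conditions while preserving each trial's input-output
#' pair, so shuffled fits can still perform the task. Correlations of each
#' fit's recurrent connectivity with the best original fit are compared
#' between arms with a one-sided Wilcoxon rank-sum test (alternative:
#' shuffled correlations are smaller).
#'
#' @param y,z,batch data as in [fit_latent()]
#' @param n_fits fits per arm
#' @param cfg base [latent_fit_config()]
#' @return list with the rank-sum `statistic`, one-sided `p_value`,
#'   per-arm correlation vectors, the per-arm fit lists and failure counts
#' @export
shuffle_test <- function(y, z, batch, n_fits = 20L,
                         cfg = latent_fit_config()) {
  split <- split_trials(batch$conditions, cfg$seed)
  fit_arm <- function(arm_y, seed_base) {
    lapply(seq_len(n_fits), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- seed_base + 1000L * i
      tryCatch(fit_latent(arm_y, z, batch, cfg_i, split = split),
               error = function(e) NULL)
    })
  }
  orig <- fit_arm(y, cfg$seed)
  K <- dim(y)[1]
  shuf <- lapply(seq_len(n_fits), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 500000L + 1000L * i
    perm <- with_seed_or_not(cfg_i$seed, sample.int(K))
    tryCatch(fit_latent(y[perm, , , drop = FALSE], z, batch, cfg_i,
                        split = split),
             error = function(e) NULL)
  })
  n_fail <- sum(vapply(orig, is.null, logical(1))) +
    sum(vapply(shuf, is.null, logical(1)))
  orig <- Filter(Negate(is.null), orig)
  shuf <- Filter(Negate(is.null), shuf)
  if (length(orig) < 2 || length(shuf) < 1) {
    stop("too many fit failures in the permutation test", call. = FALSE)
  }
  r2 <- vapply(orig, function(f) f$metrics$r2_total, numeric(1))
  best <- as.numeric(orig[[which.max(r2)]]$circuit$w_rec)
  cor_to_best <- function(fits, drop_best = FALSE) {
    ws <- lapply(fits, function(f) as.numeric(f$circuit$w_rec))
    cors <- vapply(ws, function(w) cor(best, w), numeric(1))
    if (drop_best) cors <- cors[-which.max(r2)]
    cors
  }
  cors_orig <- cor_to_best(orig, drop_best = TRUE)
  cors_shuf <- cor_to_best(shuf)
  wt <- wilcox.test(cors_shuf, cors_orig, alternative = "less",
                    exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       cors_original = cors_orig, cors_shuffled = cors_shuf,
       fits_original = orig, fits_shuffled = shuf, n_failed = n_fail)
}

#' Fraction of response variance captured by leading principal components
#'
#' Pools responses over trials and time and returns the cumulative
#' explained variance of the first `n_pcs` principal components, as a
#' percentage.
#'
#' @param y responses, trials x time x N
#' @param n_pcs number of leading components
#' @return percentage of total variance
#' @export
pc_variance_captured <- function(y, n_pcs = 8L) {
  M <- t(pool_mat(y))
  pc <- prcomp(M, center = TRUE)
  100 * sum(pc$sdev[seq_len(n_pcs)]^2) / sum(pc$sdev^2)
}

#' Psychometric slope with respect to a coherence
#'
#' Least-squares slope of the fraction of rightward choices against a
#' coherence column within one context; used to quantify decision-boundary
#' rotations under perturbations.
#'
#' @param tab psychometric table from [psychometric()]
#' @param context `"motion"` or `"color"`
#' @param coherence `"motion_coherence"` or `"color_coherence"`
#' @return scalar slope
#' @export
psychometric_slope <- function(tab, context, coherence) {
  sub <- tab[tab$context == context, ]
  m <- tapply(sub$frac_right, sub[[coherence]], mean)
  coh <- as.numeric(names(m))
  sum((coh - mean(coh)) * (m - mean(m))) / sum((coh - mean(coh))^2)
}
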