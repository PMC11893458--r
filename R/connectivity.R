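check_orthonormal <- function(Q, tol = 1e-6) {
  if (max(abs(crossprod(Q) - diag(ncol(Q)))) > tol) {
    stop("Q is not orthonormal", call. = FALSE)
  }
  invisible(Q)
}

#' Conjugate ambient connectivity into the embedding basis
#'
#' Returns `t(Q) %*% W_rec %*% Q` and `t(Q) %*% W_in`: the low-dimensional
#' connectivity structure that acts within the subspace spanned by the
#' columns of `Q`. When the embedded circuit model fits the network's
#' responses, these conjugated matrices approximate the latent circuit's
#' own connectivity -- an independent check of the inferred mechanism,
#' since fitting never sees the network's weights.
#'
#' @param W_rec `N x N` recurrent weights
#' @param W_in optional `N x c` input weights
#' @param Q orthonormal `N x n` embedding
#' @return list with `w_rec` (`n x n`) and, if `W_in` given, `w_in`
#' @export
conjugate_connectivity <- function(W_rec, Q, W_in = NULL) {
  check_orthonormal(Q)
  out <- list(w_rec = crossprod(Q, W_rec %*% Q))
  if (!is.null(W_in)) out$w_in <- crossprod(Q, W_in)
  out
}

#' Complete an orthonormal embedding to a full basis
#'
#' Extends `Q` (`N x n`) to an `N x N` orthonormal matrix whose first `n`
#' columns equal `Q`, using a seeded random complement orthogonalized
#' against `Q`, with the sign of each completed column fixed so its
#' largest-magnitude entry is positive.
#'
#' @param Q orthonormal `N x n`
#' @param seed seed for the random complement
#' @return orthonormal `N x N` matrix
#' @export
complete_basis <- function(Q, seed = 1L) {
  check_orthonormal(Q)
  N <- nrow(Q); n <- ncol(Q)
  if (n == N) return(Q)
  R <- with_seed_or_not(seed, matrix(rnorm(N * (N - n)), N))
  Qfull <- qr.Q(qr(cbind(Q, R)))
  Qfull[, seq_len(n)] <- Q
  for (j in (n + 1L):N) {
    col <- Qfull[, j]
    if (col[which.max(abs(col))] < 0) Qfull[, j] <- -col
  }
  check_orthonormal(Qfull, tol = 1e-8)
  Qfull
}

#' Map a latent connectivity perturbation onto the ambient network
#'
#' A change `delta` of the latent connection from node `j` to node `i`
#' corresponds to the rank-one ambient perturbation
#' `delta * q_i %*% t(q_j)`, where `q_i` is the `i`-th column of `Q`. The
#' matrix dot product of any ambient connectivity with this direction
#' equals the latent-space dot product with the single-entry direction, so
#' adding multiples of the image to `W_rec` changes exactly the targeted
#' latent connection (as seen through conjugation) and nothing else.
#'
#' @param Q orthonormal embedding
#' @param i target (postsynaptic) latent node
#' @param j source (presynaptic) latent node
#' @param delta signed weight change
#' @return a `perturbation_spec`: `i`, `j`, `delta` and the `N x N`
#'   `rank_one_image`
#' @export
map_perturbation <- function(Q, i, j, delta = 1) {
  n <- ncol(Q)
  if (!(i %in% seq_len(n)) || !(j %in% seq_len(n))) {
    stop("node index out of range", call. = FALSE)
  }
  structure(list(i = i, j = j, delta = delta,
                 rank_one_image = delta * tcrossprod(Q[, i], Q[, j])),
            class = "perturbation_spec")
}

#' Apply a mapped perturbation to an RNN
#'
#' Adds `scale * rank_one_image` to the recurrent weights. The Dale
#' constraint is deliberately not re-imposed: the perturbation is a probe
#' of the trained network, not a training step.
#'
#' @param params an `rnn_params`
#' @param spec a [map_perturbation()] result
#' @param scale multiplier on the image
#' @return perturbed `rnn_params`
#' @export
apply_perturbation <- function(params, spec, scale = 1) {
  params$W_rec <- params$W_rec + scale * spec$rank_one_image
  params
}

#' Psychometric functions under a swept connectivity perturbation
#'
#' Convenience sweep: for each scale, perturbs the network and recomputes
#' the psychometric table.
#'
#' @inheritParams apply_perturbation
#' @param scales multipliers to sweep
#' @param ... forwarded to [psychometric()]
#' @return data frame of psychometric tables stacked with a `scale` column
#' @export
perturbation_sweep <- function(params, spec, scales = c(0, 0.25, 0.5, 1),
                               ...) {
  out <- lapply(scales, function(s) {
    tab <- psychometric(apply_perturbation(params, spec, s), ...)
    tab$scale <- s
    tab
  })
  do.call(rbind, out)
}

#' Stimulate network activity along an axis
#'
#' Injects `magnitude * axis` as extra current inside the rectifier at
#' every step of the stimulus epoch, then reads out choices. Used to
#' compare the behavioral potency of activity patterns, e.g. a latent
#' sensory axis versus a decoder axis, at matched Euclidean magnitude.
#'
#' @param params an `rnn_params`
#' @param axis length-`N` direction, unit norm
#' @param magnitude stimulation strength
#' @param n_per_condition,seed,task,conditions forwarded to
#'   [psychometric()]
#' @return psychometric table under stimulation
#' @export
stimulate_along_axis <- function(params, axis, magnitude,
                                 n_per_condition = 20L, seed = 1L,
                                 task = ctx_dm_task(),
                                 conditions = ctx_dm_conditions()) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis has zero norm", call. = FALSE)
  axis <- axis / nrm
  make_ext <- function(batch) {
    K <- dim(batch$u)[1]; Tn <- dim(batch$u)[2]
    ext <- array(0, c(K, Tn, params$N))
    for (t in which(task$stim_steps)) {
      ext[, t, ] <- matrix(magnitude * axis, K, params$N, byrow = TRUE)
    }
    ext
  }
  psychometric(params, n_per_condition, seed, task, conditions,
               ext = make_ext)
}
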