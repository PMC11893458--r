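# Minimal Adam optimizer over a named list of parameter matrices, with
# classic L2 weight decay added to the gradient (as in the reference
# training setup). Kept internal; both the RNN trainer and the latent
# circuit fitter drive it.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Orthogonality penalty on the column-normalized concatenation of input and
# output weight vectors: lambda * sum of squared off-diagonal entries of the
# Gram matrix. Returns the penalty value and its gradient with respect to
# the unnormalized matrix whose columns are the input/output vectors.
orth_penalty <- function(Bio, lambda) {
  nrm <- sqrt(colSums(Bio^2))
  nrm[nrm == 0] <- 1
  Bn <- sweep(Bio, 2, nrm, "/")
  G <- crossprod(Bn)
  off <- G - diag(diag(G))
  value <- lambda * sum(off^2)
  # d/dBn of sum(off^2) = 4 Bn off; chain through column normalization
  dBn <- 4 * lambda * (Bn %*% off)
  dBio <- sweep(dBn - sweep(Bn, 2, colSums(dBn * Bn), "*"), 2, nrm, "/")
  list(value = value, grad = dBio)
}
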