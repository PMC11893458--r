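# Internal array plumbing. User-facing response arrays are [trials x time x
# units]; the C++ kernels consume cubes with [units x trials x time].

# [K,T,C] array -> C x K x T cube
to_cube <- function(x) aperm(x, c(3L, 1L, 2L))

# m x K x (T+1) state cube (slice 1 = initial state) -> [K,T,m] array
from_state_cube <- function(Y) {
  Tn <- dim(Y)[3] - 1L
  aperm(Y[, , seq_len(Tn) + 1L, drop = FALSE], c(2L, 3L, 1L))
}

# m x K x T cube -> [K,T,m]
from_cube <- function(X) aperm(X, c(2L, 3L, 1L))

# pooled K*T-column matrix (m x KT) from [K,T,m] array; column order matches
# cube element order (trial fastest, then time)
pool_mat <- function(x) {
  d <- dim(x)
  t(matrix(x, d[1] * d[2], d[3]))
}

# run expr under a temporary RNG state; NULL seed leaves the RNG alone
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# coefficient of determination, pooled over all entries
r_squared <- function(obs, fit) {
  obs <- as.numeric(obs); fit <- as.numeric(fit)
  1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
}

# ratio of residual to total sum of squares, the normalized residual used in
# the neural-data loss
ss_ratio <- function(resid, ref) sum(resid^2) / sum(ref^2)

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}
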