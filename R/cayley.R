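#' Orthonormal embedding via the Cayley transform
#'
#' Maps an arbitrary square matrix `B` to a tall orthonormal matrix: the
#' skew-symmetric `A = B - t(B)` is passed through the Cayley transform
#' `C = (I + A) (I - A)^{-1}` (orthogonal for any skew-symmetric `A`, since
#' `I - A` is always invertible), and the first `n` columns are returned.
#' This turns optimization over the Stiefel manifold of orthonormal
#' embeddings into unconstrained optimization over `B`. The parameterization
#' is degenerate (`A` has only `N(N-1)/2` distinct entries) but harmless,
#' as only `Q` enters the model.
#'
#' @param B arbitrary `N x N` matrix
#' @param n number of leading columns to keep
#' @return `N x n` matrix `Q` with `t(Q) %*% Q = I` to machine precision
#' @export
cayley_embed <- function(B, n) {
  N <- nrow(B)
  if (n > N) stop("n must not exceed nrow(B)", call. = FALSE)
  A <- B - t(B)
  In <- diag(N)
  (In + A) %*% solve(In - A, In[, seq_len(n), drop = FALSE])
}

# Backward pass of the Cayley embedding: given dL/dQ, return dL/dB.
# With C = (I+A)(I-A)^{-1} and M = (I-A)^{-1}, the differential is
# dC = (I + C) dA M, so dL/dA = t(I + C) G t(M) with G the zero-padded
# dL/dQ, and dL/dB = dL/dA - t(dL/dA).
cayley_backward <- function(B, dQ) {
  N <- nrow(B)
  A <- B - t(B)
  M <- solve(diag(N) - A)
  C <- (diag(N) + A) %*% M
  G <- matrix(0, N, N)
  G[, seq_len(ncol(dQ))] <- dQ
  dA <- t(diag(N) + C) %*% G %*% t(M)
  dA - t(dA)
}
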