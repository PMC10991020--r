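# Shared fixtures: small random problems built in code under fixed seeds.

random_centered <- function(I, J, seed = 1, col_scale = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(I * J), I, J)
  if (col_scale) X <- X %*% diag(runif(J, 0.5, 2))
  center_columns(X)
}

# exact low-rank matrix with known orthonormal scores and sparse loadings
rank_r_sparse_loadings <- function(I, J, R, k, seed = 1) {
  set.seed(seed)
  T0 <- qr.Q(qr(center_columns(matrix(rnorm(I * R), I, R))))
  P <- matrix(0, J, R)
  for (r in seq_len(R)) {
    P[sample.int(J, k), r] <- runif(k, 0.5, 2) * sample(c(-1, 1), k, TRUE)
  }
  list(X = T0 %*% t(P), T = T0, P = P)
}

expect_orthonormal <- function(M, tol = 1e-8) {
  expect_lt(max(abs(crossprod(M) - diag(ncol(M)))), tol)
}
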