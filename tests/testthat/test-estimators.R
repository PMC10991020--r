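test_that("pca_svd equals the right singular vectors in both blocks", {
  X <- random_centered(20, 6, seed = 11, col_scale = TRUE)
  fit <- pca_svd(X, 3)
  sv <- svd(X)
  V <- sv$v[, 1:3]
  V <- sweep(V, 2, spcawl:::component_signs(V), "*")
  expect_equal(fit$W, V, tolerance = 1e-10)
  expect_equal(fit$P, V, tolerance = 1e-10)
  expect_equal(fit$T, X %*% V, tolerance = 1e-8)
  # full-rank decomposition explains everything
  expect_equal(pca_svd(X, 6)$vaf_total, 1, tolerance = 1e-10)
  # orthogonal columns of distinct norms: V is the identity (up to order)
  D <- center_columns(qr.Q(qr(matrix(rnorm(40), 10, 4)))[, 1:3] %*%
                        diag(c(3, 2, 1)))
  expect_error(pca_svd(D, 5), "`R` must be")
})

test_that("spca constraints hold: orthonormal loadings, cardinality bound", {
  set.seed(12)
  for (i in 1:10) {
    I <- sample(15:30, 1); J <- sample(6:12, 1); q <- sample(2:4, 1)
    X <- random_centered(I, J, seed = 100 + i)
    P0 <- matrix(runif(J * 2, -1, 1), J, 2)
    fit <- fit_spca(X, 2, q, P_init = P0, lambda2 = 1e-6)
    expect_orthonormal(fit$P)
    expect_true(all(colSums(fit$W != 0) <= q))
    expect_equal(fit$T, X %*% fit$W, tolerance = 1e-10)
  }
})

test_that("spca with q = J and no penalties reproduces the PCA subspace", {
  X <- random_centered(25, 5, seed = 13)
  fit <- fit_spca(X, 2, nonzeros = 5, lambda = 0, lambda2 = 0)
  pca <- pca_svd(X, 2)
  expect_equal(fit$recon, pca$loss, tolerance = 1e-8)
  expect_equal(fit$vaf_total, pca$vaf_total, tolerance = 1e-8)
})

test_that("uslpca constraints hold: orthonormal scores, exact cardinality", {
  set.seed(14)
  for (i in 1:10) {
    I <- sample(15:30, 1); J <- sample(6:12, 1); k <- sample(2:4, 1)
    X <- random_centered(I, J, seed = 200 + i)
    P0 <- matrix(runif(J * 2, -1, 1), J, 2)
    fit <- fit_uslpca(X, 2, k, P_init = P0)
    expect_orthonormal(fit$T)
    expect_equal(colSums(fit$P != 0), rep(k, 2))
  }
})

test_that("uslpca with k = J attains the PCA residual", {
  X <- random_centered(25, 5, seed = 15)
  fit <- fit_uslpca(X, 2, nonzeros = 5)
  expect_equal(fit$loss, pca_svd(X, 2)$loss, tolerance = 1e-8)
})

test_that("uslpca loss trajectory is non-increasing on random instances", {
  set.seed(16)
  for (i in 1:100) {
    I <- sample(12:25, 1); J <- sample(5:10, 1)
    X <- random_centered(I, J, seed = 300 + i, col_scale = TRUE)
    k <- sample(2:(J - 1), 1)
    fit <- fit_uslpca(X, 2, k,
                      P_init = matrix(runif(J * 2, -1, 1), J, 2))
    expect_lte(max(diff(fit$loss_trajectory)),
               1e-8 * max(1, fit$loss_trajectory[1]))
  }
})

test_that("spca loadings half-step never increases the reconstruction loss", {
  # the weight update targets its own knot penalty, so the full objective is
  # not monotone; the Procrustes update, given W, is an exact minimizer
  set.seed(17)
  for (i in 1:100) {
    I <- sample(12:25, 1); J <- sample(5:10, 1)
    X <- random_centered(I, J, seed = 400 + i)
    W <- matrix(rnorm(J * 2) * rbinom(J * 2, 1, 0.5), J, 2)
    if (all(W == 0)) W[1, 1] <- 1
    P_opt <- spcawl:::polar_safe(crossprod(X) %*% W)
    loss_opt <- sum((X - X %*% W %*% t(P_opt))^2)
    for (j in 1:5) {
      Q <- qr.Q(qr(matrix(rnorm(J * 2), J, 2)))
      expect_lte(loss_opt, sum((X - X %*% W %*% t(Q))^2) + 1e-8)
    }
  }
})

test_that("spca keeps the best iterate: more iterations never hurt", {
  X <- random_centered(30, 8, seed = 18)
  P0 <- matrix(runif(16, -1, 1), 8, 2)
  recons <- vapply(c(5, 20, 80, 200), function(m) {
    fit_spca(X, 2, 3, P_init = P0, lambda2 = 1e-6, max_iter = m)$recon
  }, numeric(1))
  expect_true(all(diff(recons) <= 1e-10))
})

test_that("weights_from_scores is the minimum-norm least-squares solution", {
  # full column rank: recovers the generating weights exactly
  X <- random_centered(20, 5, seed = 19)
  W0 <- matrix(rnorm(10), 5, 2)
  expect_equal(weights_from_scores(X, X %*% W0), W0, tolerance = 1e-8)
  # J > I: any null-space perturbation has larger Frobenius norm
  X2 <- random_centered(6, 10, seed = 20)
  T2 <- X2 %*% matrix(rnorm(20), 10, 2)
  W <- weights_from_scores(X2, T2)
  expect_lt(max(abs(X2 %*% W - T2)), 1e-8)
  null_basis <- svd(X2, nv = 10)$v[, 6:10]
  set.seed(21)
  for (i in 1:10) {
    Wp <- W + null_basis %*% matrix(rnorm(10, sd = 0.3), 5, 2)
    expect_lt(max(abs(X2 %*% Wp - T2)), 1e-6) # still an exact solution
    expect_lt(sum(W^2), sum(Wp^2))            # but never smaller in norm
  }
})

test_that("objective_value recomputes the criteria from the fit", {
  X <- random_centered(20, 6, seed = 22)
  fu <- fit_uslpca(X, 2, 3)
  expect_equal(objective_value(fu, X), fu$loss, tolerance = 1e-10)
  fs <- fit_spca(X, 2, 3, lambda = 2, lambda2 = 0)
  expect_equal(objective_value(fs, X), fs$loss, tolerance = 1e-8)
  expect_equal(objective_value(fs, X, lambda = 0, lambda2 = 0), fs$recon,
               tolerance = 1e-8)
  # exact reconstruction gives a zero least-squares objective
  lr <- rank_r_sparse_loadings(15, 6, 2, 3, seed = 23)
  exact <- spcawl:::new_spca_fit("uslpca", lr$X,
                                 W = weights_from_scores(lr$X, lr$T),
                                 P = lr$P, T_scores = lr$T, loss = 0,
                                 recon = 0, loss_trajectory = 0, n_iter = 1L,
                                 converged = TRUE)
  expect_lt(objective_value(exact, lr$X), 1e-16)
})

test_that("estimators validate their inputs", {
  X <- random_centered(10, 4, seed = 24)
  expect_error(fit_spca(X, 5, 2), "`R` must be")
  expect_error(fit_spca(X, 2, 0), "`nonzeros`")
  expect_error(fit_uslpca(X, 2, 9), "`nonzeros`")
  expect_error(fit_uslpca(X, 2, 2, P_init = matrix(1, 3, 2)), "J x R")
})
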