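test_that("make_sparse_orthonormal produces disjoint orthonormal supports", {
  set.seed(51)
  # J=3, R=2, one non-zero per column: supports partition all but one variable
  V <- make_sparse_orthonormal(3, 2, 2/3)
  expect_equal(colSums(V != 0), c(1, 1))
  expect_length(intersect(which(V[, 1] != 0), which(V[, 2] != 0)), 0)
  expect_orthonormal(V, 1e-12)
  # dense single column
  v1 <- make_sparse_orthonormal(5, 1, 0)
  expect_equal(sum(v1 != 0), 5)
  expect_equal(sum(v1^2), 1, tolerance = 1e-12)
  # J=50, R=2, 90% sparsity: 5 non-zeros per column, exact orthonormality
  V2 <- make_sparse_orthonormal(50, 2, 0.9)
  expect_equal(colSums(V2 != 0), c(5, 5))
  expect_lt(max(abs(crossprod(V2) - diag(2))), 1e-12)
  expect_length(intersect(which(V2[, 1] != 0), which(V2[, 2] != 0)), 0)
  # uniform value variant keeps the same structure
  V3 <- make_sparse_orthonormal(50, 2, 0.9, values = "uniform")
  expect_equal(colSums(V3 != 0), c(5, 5))
  expect_orthonormal(V3, 1e-12)
  # infeasible request errors
  expect_error(make_sparse_orthonormal(10, 3, 0.5), "disjoint supports")
})

test_that("scale_error_to_pev realizes the ratio exactly", {
  set.seed(52)
  Xm <- matrix(rnorm(50), 10, 5)
  Er <- matrix(rnorm(50), 10, 5)
  expect_equal(scale_error_to_pev(Xm, Er, 0), matrix(0, 10, 5))
  # ||X_model||^2 = 9, pev = 0.1 => ||E||^2 = 1
  Xm9 <- matrix(3, 1, 1); Xm9 <- rbind(Xm9, 0) # 2x1 with ss 9
  E1 <- matrix(c(1, 1), 2, 1)
  E <- scale_error_to_pev(Xm9, E1, 0.1)
  expect_equal(sum(E^2), 1, tolerance = 1e-12)
  # self-check across pev values
  for (pev in c(0.05, 0.1, 0.5, 0.9)) {
    E <- scale_error_to_pev(Xm, Er, pev)
    expect_equal(sum(E^2) / (sum(Xm^2) + sum(E^2)), pev, tolerance = 1e-12)
  }
  expect_error(scale_error_to_pev(Xm, Er, 1), "must be in")
  expect_error(scale_error_to_pev(Xm, 0 * Er, 0.2), "zero")
})

test_that("generated datasets satisfy the ground-truth invariants", {
  for (model in c("spiked_covariance", "sparse_loadings", "sparse_weights")) {
    for (pev in c(0, 0.5)) {
      cfg <- dgm_config(model, I = 40, J = 20, R = 2, sparsity = 0.8,
                        pev = pev, seed = 60)
      tr <- generate_dataset(cfg)
      # columns of E orthogonal to columns of X_model
      cross <- crossprod(tr$X_model, tr$E)
      expect_lt(max(abs(cross)) / max(sum(tr$X_model^2), 1), 1e-10)
      # realized error share is exact
      if (pev > 0) {
        expect_equal(sum(tr$E^2) / sum(tr$X^2), pev, tolerance = 1e-10)
      } else {
        expect_lt(max(abs(tr$X - tr$X_model)), 1e-12)
      }
      # X centered; sparsity bookkeeping exact
      expect_lt(max(abs(colMeans(tr$X))), 1e-12)
      expect_equal(sum(tr$true_sparse == 0), (20 - tr$k) * 2)
      expect_equal(colSums(tr$true_sparse != 0), rep(tr$k, 2))
    }
  }
})

test_that("generation is bit-identical under equal config and seed", {
  cfg <- dgm_config("sparse_weights", I = 30, J = 15, R = 2, sparsity = 0.5,
                    pev = 0.1, seed = 61)
  t1 <- generate_dataset(cfg)
  t2 <- generate_dataset(cfg)
  expect_identical(t1$X, t2$X)
  expect_identical(t1$true_sparse, t2$true_sparse)
  t3 <- generate_dataset(dgm_config("sparse_weights", 30, 15, 2,
                                    sparsity = 0.5, pev = 0.1, seed = 62))
  expect_false(identical(t1$X, t3$X))
})

test_that("spiked model at pev = 0: X V_R reproduces the true scores", {
  cfg <- dgm_config("spiked_covariance", I = 40, J = 20, R = 2,
                    sparsity = 0.8, pev = 0, seed = 63)
  tr <- generate_dataset(cfg)
  expect_equal(tr$X %*% tr$true_sparse, tr$true_scores, tolerance = 1e-10)
})

test_that("noiseless low-rank data is reconstructed by its true structure", {
  for (model in c("spiked_covariance", "sparse_loadings")) {
    cfg <- dgm_config(model, I = 40, J = 20, R = 2, sparsity = 0.8,
                      pev = 0, seed = 64)
    tr <- generate_dataset(cfg)
    Q <- qr.Q(qr(tr$true_sparse))
    expect_lt(max(abs(tr$X %*% Q %*% t(Q) - tr$X)), 1e-10)
  }
})

test_that("sparse-weights model with J > I exhibits weight indeterminacy", {
  cfg <- dgm_config("sparse_weights", I = 10, J = 20, R = 2, sparsity = 0.5,
                    pev = 0, seed = 65)
  tr <- generate_dataset(cfg)
  W1 <- tr$true_sparse
  # add a null-space vector of X to one weight column: scores are unchanged
  nullv <- svd(tr$X, nv = 20)$v[, 20]
  expect_lt(max(abs(tr$X %*% nullv)), 1e-8)
  W2 <- W1
  W2[, 1] <- W2[, 1] + nullv
  expect_false(isTRUE(all.equal(W1, W2)))
  expect_equal(tr$X %*% W1, tr$X %*% W2, tolerance = 1e-8)
})

test_that("correlated initial matrix option changes the data, not the contract", {
  cfg <- dgm_config("spiked_covariance", I = 40, J = 10, R = 2,
                    sparsity = 0.5, pev = 0.1, correlated_init = TRUE,
                    ar_rho = 0.6, seed = 66)
  tr <- generate_dataset(cfg)
  expect_lt(max(abs(colMeans(tr$X))), 1e-12)
  expect_equal(sum(tr$E^2) / sum(tr$X^2), 0.1, tolerance = 1e-10)
})

test_that("config validation catches infeasible requests", {
  expect_error(dgm_config("spiked_covariance", I = 10, J = 4, R = 2,
                          sparsity = 0.99, pev = 0), "no non-zero")
  expect_error(dgm_config("spiked_covariance", I = 10, J = 10, R = 2,
                          sparsity = 0.2, pev = 0), "infeasible")
  expect_error(dgm_config("sparse_weights", I = 2, J = 10, R = 2,
                          sparsity = 0.5, pev = 0), "I > R")
  expect_error(dgm_config("sparse_weights", I = 10, J = 10, R = 2,
                          sparsity = 0.5, pev = 1.2), "pev")
})

test_that("toy dataset matches its printed values and exact reconstruction", {
  toy <- toy_dataset()
  expect_equal(toy$X[1, ], c(0.63, 0.52, 0.11))
  expect_equal(colSums(toy$X), rep(0, 3))
  expect_equal(toy$P, matrix(c(2, 0, 1.41, 1.41, 0, 2), 3, 2, byrow = TRUE))
  expect_equal(colSums(toy$P == 0), c(1, 1))
  # printed scores are orthonormal within printed rounding
  expect_lt(max(abs(crossprod(toy$T) - diag(2))), 0.01)
  # exact reconstruction: centered, ||X||^2 = 12, X'X = PP', close to print
  expect_lt(max(abs(colMeans(toy$X_exact))), 1e-12)
  expect_equal(sum(toy$X_exact^2), 12, tolerance = 1e-10)
  expect_equal(crossprod(toy$X_exact), tcrossprod(toy$P_exact),
               tolerance = 1e-10)
  expect_lt(max(abs(toy$X_exact - toy$X)), 0.012)
})
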