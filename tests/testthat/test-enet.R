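test_that("single-variable response is picked up exactly", {
  set.seed(1)
  Z <- matrix(rnorm(60), 12, 5)
  y <- 3 * Z[, 5]
  b <- cardinality_enet(Z, y, q = 1, lambda2 = 0)
  expect_equal(which(b != 0), 5L)
  # path terminates at the exact fit, so the coefficient is unshrunk
  expect_equal(b[5], 3, tolerance = 1e-8)
})

test_that("unrestricted path run to the end gives ordinary least squares", {
  set.seed(2)
  Z <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  b <- cardinality_enet(Z, y, q = 4, lambda2 = 0)
  expect_equal(b, as.vector(qr.coef(qr(Z), y)), tolerance = 1e-8)
})

test_that("degenerate inputs are tolerated", {
  set.seed(3)
  Z <- matrix(rnorm(40), 10, 4)
  expect_equal(cardinality_enet(Z, rep(0, 10), q = 2), rep(0, 4))
  Z[, 2] <- 0 # a dead predictor can never enter
  b <- cardinality_enet(Z, rnorm(10), q = 4)
  expect_equal(b[2], 0)
})

test_that("truncated path matches glmnet at the knot (lasso, q nonzeros)", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  for (i in 1:10) {
    n <- 30; J <- 8; q <- sample(2:5, 1)
    Z <- matrix(rnorm(n * J), n, J)
    y <- Z %*% (rnorm(J) * rbinom(J, 1, 0.6)) + rnorm(n, sd = 0.3)
    b <- cardinality_enet(Z, y, q = q, lambda2 = 0)
    act <- which(b != 0)
    expect_lte(length(act), q)
    # the knot's lambda satisfies the KKT conditions: 2*Z'r = lambda*sign(b)
    r <- y - Z %*% b
    corr <- as.vector(crossprod(Z, r))
    lam <- 2 * max(abs(corr))
    expect_lt(max(abs(2 * corr[act] - lam * sign(b[act]))), 1e-6 * lam)
    # glmnet's solution at that lambda (objective/(2n) scaling) agrees
    g <- glmnet::glmnet(Z, y, alpha = 1, lambda = lam / (2 * n),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    expect_equal(b, as.vector(g$beta), tolerance = 1e-4)
  }
})

test_that("ridge augmentation solves the naive elastic net", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 25; J <- 6; lambda2 <- 0.7
  Z <- matrix(rnorm(n * J), n, J)
  y <- Z %*% c(2, -1, 0, 0, 1, 0) + rnorm(n, sd = 0.2)
  b <- cardinality_enet(Z, y, q = 3, lambda2 = lambda2)
  expect_lte(sum(b != 0), 3)
  # oracle: plain lasso on the explicitly ridge-augmented data at the knot
  Zaug <- rbind(Z, sqrt(lambda2) * diag(J))
  yaug <- c(y, rep(0, J))
  r <- yaug - Zaug %*% b
  lam <- 2 * max(abs(crossprod(Zaug, r)))
  g <- glmnet::glmnet(Zaug, yaug, alpha = 1, lambda = lam / (2 * nrow(Zaug)),
                      standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  expect_equal(b, as.vector(g$beta), tolerance = 1e-4)
})

test_that("active set matches the brute-force subset oracle on a 6x4 problem", {
  # enumerate all 2-subsets; the knot solution's active set must attain the
  # best elastic-net objective at the knot's lambda among all 2-subsets
  set.seed(6)
  for (rep in 1:5) {
    Z <- matrix(rnorm(24), 6, 4)
    y <- Z %*% c(1.5, 0, -2, 0) + rnorm(6, sd = 0.1)
    q <- 2
    b <- cardinality_enet(Z, y, q = q, lambda2 = 0)
    act <- sort(which(b != 0))
    r <- y - Z %*% b
    lam <- 2 * max(abs(crossprod(Z, r)))
    obj <- function(beta) sum((y - Z %*% beta)^2) + lam * sum(abs(beta))
    best <- Inf; best_sets <- list()
    for (s in asplit(combn(4, q), 2)) {
      # lasso restricted to subset s at penalty lam, by coordinate descent
      G <- crossprod(Z[, s, drop = FALSE])
      bb <- spcawl:::cd_enet_fixed(G, as.vector(crossprod(Z[, s], y)), lam)
      beta <- numeric(4); beta[s] <- bb
      o <- obj(beta)
      if (o < best - 1e-10) { best <- o; best_sets <- list(sort(s[bb != 0])) }
      else if (o < best + 1e-10) best_sets <- c(best_sets, list(sort(s[bb != 0])))
    }
    expect_true(any(vapply(best_sets, identical, logical(1), act)))
    expect_equal(obj(b), best, tolerance = 1e-6)
  }
})

test_that("coordinate-descent fallback reaches the same active set as LARS-EN", {
  set.seed(7)
  for (i in 1:20) {
    n <- 20 + i; J <- sample(4:10, 1); q <- sample(1:(J - 1), 1)
    l2 <- sample(c(0, 0.3), 1)
    Z <- matrix(rnorm(n * J), n, J)
    y <- Z %*% (rnorm(J) * rbinom(J, 1, 0.5)) + rnorm(n, sd = 0.5)
    b1 <- cardinality_enet(Z, y, q, lambda2 = l2, solver = "lars")
    b2 <- cardinality_enet(Z, y, q, lambda2 = l2, solver = "cd")
    expect_equal(which(b1 != 0), which(abs(b2) > 1e-8 * max(abs(b2), 1)),
                 info = paste("instance", i))
    expect_equal(b1, b2, tolerance = 1e-4)
  }
})

test_that("compiled LARS-EN kernel agrees exactly with the R reference", {
  set.seed(8)
  for (i in 1:50) {
    J <- sample(3:12, 1); n <- J + sample(1:10, 1)
    Z <- matrix(rnorm(n * J), n, J)
    y <- rnorm(n); q <- sample(1:J, 1); l2 <- sample(c(0, 0.5), 1)
    G <- crossprod(Z) + diag(l2, J)
    b <- as.vector(crossprod(Z, y))
    expect_equal(spcawl:::larsen_gram(G, b, q),
                 spcawl:::larsen_gram_r(G, b, q), tolerance = 1e-10)
  }
})
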