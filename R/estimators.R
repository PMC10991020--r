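#' Sparse-weights PCA (elastic-net penalized, exact cardinality control)
#'
#' Alternating least-squares estimator for the criterion
#' \deqn{\|X - XW_R P_R'\|_F^2 + \lambda \sum_r \|w_r\|_1 +
#'       \lambda_2 \sum_r \|w_r\|_2^2 \quad \mathrm{s.t.}\; P_R'P_R = I_R,}
#' where sparsity lives in the weights: each weight column is updated by an
#' elastic-net regression of the current component `X p_r` on the variables,
#' solved by a LARS-EN path truncated so that at most `nonzeros` coefficients
#' are active (see [cardinality_enet()]); the loadings are then the
#' orthonormal Procrustes solution `polar(X'X W)`. The lasso weight `lambda`
#' is a *reporting* parameter: the cardinality bound plays the role of the
#' `l1` tuning along the path, and `lambda` only enters the recorded
#' objective, as in the common practice of specifying the number of non-zero
#' weights directly.
#'
#' The alternation is monitored on the reconstruction loss
#' `||X - X W P'||_F^2` (the quantity the updates act on); iteration stops
#' when its relative change falls below `tol`. Because the truncated-path
#' weight update is not the minimizer of any fixed-penalty objective, the
#' alternation can cycle among near-equivalent knot solutions on noisy data
#' instead of settling; in that regime the iteration cap is the effective
#' stop (`converged = FALSE`) and the reported solution is the best iterate
#' by reconstruction loss. The full objective is recorded per iteration in
#' `loss_trajectory`.
#'
#' @param X Numeric data matrix; columns are centered internally.
#' @param R Number of components.
#' @param nonzeros Maximum number of non-zero weights per component. The
#'   bound is an upper bound: a path can terminate with fewer active
#'   variables (the toy example's first component does exactly that).
#' @param P_init Initial `J x R` loadings; defaults to the right singular
#'   vectors `V_R` of `X` (the "SVD-based" start).
#' @param lambda Reporting lasso weight used in `loss`.
#' @param lambda2 Ridge weight; stabilizes the weight update with correlated
#'   or high-dimensional (`J > I`) data.
#' @param max_iter,tol Iteration cap and relative-loss-change threshold.
#' @param solver Inner elastic-net solver, see [cardinality_enet()].
#' @param init_label Free-text label stored in the fit (used by the
#'   multistart machinery).
#' @return An `spca_fit`; `W` is sparse, `P` has orthonormal columns
#'   (`P'P = I` to 1e-8), `T = X W`.
#' @references Zou, Hastie and Tibshirani (2006) Sparse principal component
#'   analysis. JCGS 15(2), 265--286.
#' @examples
#' X <- center_columns(matrix(rnorm(100), 20, 5))
#' fit <- fit_spca(X, R = 2, nonzeros = 2)
#' colSums(fit$W != 0)
#' @export
fit_spca <- function(X, R, nonzeros, P_init = NULL, lambda = 2,
                     lambda2 = 0, max_iter = 200L, tol = 1e-8,
                     solver = c("lars", "cd"), init_label = "svd") {
  solver <- match.arg(solver)
  X <- center_columns(X)
  I <- nrow(X); J <- ncol(X)
  if (R < 1 || R > min(I, J)) stop("`R` must be in 1..min(I, J)", call. = FALSE)
  if (nonzeros < 1 || nonzeros > J) stop("`nonzeros` must be in 1..J", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)

  sv <- svd(X, nu = 0, nv = R)
  if (is.null(P_init)) P_init <- sv$v
  P_init <- as.matrix(P_init)
  if (!all(dim(P_init) == c(J, R))) stop("`P_init` must be J x R", call. = FALSE)

  G <- crossprod(X)
  Gq <- if (lambda2 > 0) G + diag(lambda2, J) else G
  ssX <- sum(X^2)

  if (solver == "lars") {
    res <- spca_als_cpp(G, Gq, P_init, sv$v, ssX, as.integer(nonzeros),
                        lambda, lambda2, as.integer(max_iter), tol)
  } else {
    res <- spca_als_r(G, Gq, P_init, sv$v, ssX, nonzeros, lambda, lambda2,
                      max_iter, tol, solver)
  }
  new_spca_fit("spca", X, W = res$W, P = res$P,
               T_scores = X %*% res$W,
               loss = res$obj, recon = res$recon,
               loss_trajectory = as.numeric(res$trajectory),
               n_iter = res$n_iter, converged = res$converged,
               init_label = init_label,
               lambda = lambda, lambda2 = lambda2,
               nonzeros = as.integer(nonzeros), reseeded = res$reseeded)
}

# Pure-R mirror of the compiled alternating loop, used when an alternative
# inner solver is requested and as an oracle in the test suite.
spca_als_r <- function(G, Gq, P_init, V_svd, ssX, q, lambda, lambda2,
                       max_iter, tol, solver = "lars") {
  J <- nrow(G); R <- ncol(P_init)
  inner <- if (solver == "cd") cd_enet_gram else larsen_gram_r
  P <- P_init
  W <- matrix(0, J, R)
  traj <- numeric(0)
  best <- NULL
  recon_prev <- Inf
  converged <- FALSE
  reseeded <- 0L
  for (it in seq_len(max_iter)) {
    for (r in seq_len(R)) {
      b <- as.vector(G %*% P[, r])
      w <- inner(Gq, b, q)
      if (all(w == 0) && any(b != 0)) {
        w <- inner(Gq, as.vector(G %*% V_svd[, r]), q)
        reseeded <- reseeded + 1L
      }
      W[, r] <- w
    }
    P <- polar_safe(G %*% W)
    GW <- G %*% W
    recon <- max(ssX - 2 * sum(P * GW) + sum(W * GW), 0)
    obj <- recon + lambda * sum(abs(W)) + lambda2 * sum(W^2)
    if (is.nan(obj)) stop("objective became NaN", call. = FALSE)
    traj <- c(traj, obj)
    if (is.null(best) || recon < best$recon) {
      best <- list(W = W, P = P, recon = recon, obj = obj)
    }
    if (is.finite(recon_prev) &&
        abs(recon_prev - recon) <= tol * max(recon_prev, ssX * 1e-12)) {
      converged <- TRUE
      break
    }
    recon_prev <- recon
  }
  list(W = best$W, P = best$P, recon = best$recon, obj = best$obj,
       trajectory = traj, n_iter = it, converged = converged,
       reseeded = reseeded)
}

#' Sparse-loadings PCA (cardinality-constrained, orthonormal scores)
#'
#' Alternating least-squares estimator for
#' \deqn{\|X - T_R P_R'\|_F^2 \quad \mathrm{s.t.}\; T_R'T_R = I_R,\;
#'       \mathrm{Card}(p_r) = k,}
#' i.e. unpenalized sparse-loadings PCA. Both half-steps are exact
#' minimizers, so the loss is non-increasing: given `P`, the orthonormal
#' scores are the polar factor of `X P`; given `T`, the unconstrained
#' loadings are the univariate regressions `X'T`, and the cardinality
#' constraint is met by keeping the `k` largest-magnitude entries per column
#' (magnitude ties are resolved toward the lowest variable index,
#' deterministically). Weights are not part of the model; the returned `W`
#' is inferred post hoc via [weights_from_scores()].
#'
#' @param X Numeric data matrix; columns are centered internally.
#' @param R Number of components.
#' @param nonzeros Exact number of non-zero loadings per component
#'   (`Card(p_r) = k`).
#' @param P_init Initial `J x R` loadings; defaults to the right singular
#'   vectors of `X`.
#' @param max_iter,tol Iteration cap and relative-loss-change threshold.
#' @param init_label Label stored in the fit.
#' @return An `spca_fit`; `P` is sparse with exactly `nonzeros` non-zeros per
#'   column, `T` has orthonormal columns, `W = X^+ T`.
#' @references Adachi and Trendafilov (2016) Sparse principal component
#'   analysis subject to prespecified cardinality of loadings.
#'   Computational Statistics 31, 1403--1427.
#' @examples
#' X <- center_columns(matrix(rnorm(100), 20, 5))
#' fit <- fit_uslpca(X, R = 2, nonzeros = 3)
#' colSums(fit$P != 0)
#' @export
fit_uslpca <- function(X, R, nonzeros, P_init = NULL, max_iter = 500L,
                       tol = 1e-8, init_label = "svd") {
  X <- center_columns(X)
  I <- nrow(X); J <- ncol(X)
  if (R < 1 || R > min(I, J)) stop("`R` must be in 1..min(I, J)", call. = FALSE)
  if (nonzeros < 1 || nonzeros > J) stop("`nonzeros` must be in 1..J", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)

  sv <- svd(X, nu = 0, nv = R)
  if (is.null(P_init)) P_init <- sv$v
  P_init <- as.matrix(P_init)
  if (!all(dim(P_init) == c(J, R))) stop("`P_init` must be J x R", call. = FALSE)

  ssX <- sum(X^2)
  P <- P_init
  traj <- numeric(0)
  best <- NULL
  loss_prev <- Inf
  converged <- FALSE
  reseeded <- 0L
  for (it in seq_len(max_iter)) {
    T_scores <- polar_safe(X %*% P)
    Pt <- crossprod(X, T_scores)
    P <- hard_threshold_columns(Pt, nonzeros)
    for (r in seq_len(R)) {
      if (all(P[, r] == 0)) { # degenerate component: reseed from SVD direction
        P[, r] <- hard_threshold_columns(sv$v[, r, drop = FALSE], nonzeros)
        reseeded <- reseeded + 1L
      }
    }
    loss <- sum((X - T_scores %*% t(P))^2)
    if (is.nan(loss)) stop("loss became NaN", call. = FALSE)
    traj <- c(traj, loss)
    if (is.null(best) || loss < best$loss) best <- list(T = T_scores, P = P, loss = loss)
    if (is.finite(loss_prev) &&
        abs(loss_prev - loss) <= tol * max(loss_prev, ssX * 1e-12)) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
  }
  W <- weights_from_scores(X, best$T)
  new_spca_fit("uslpca", X, W = W, P = best$P, T_scores = best$T,
               loss = best$loss, recon = best$loss, loss_trajectory = traj,
               n_iter = it, converged = converged, init_label = init_label,
               nonzeros = as.integer(nonzeros), reseeded = reseeded)
}

#' Infer component weights from fitted scores
#'
#' The sparse-loadings model does not estimate weights; they can be recovered
#' by regressing the component scores on the data. This returns the
#' minimum-norm least-squares solution `W = X^+ T` (Moore-Penrose
#' pseudoinverse), so that `X W` best approximates `T`; with `J > I` the
#' solution of minimum Frobenius norm among all exact solutions is returned.
#'
#' @param X Centered data matrix.
#' @param T_scores `I x R` matrix of component scores.
#' @return A `J x R` weights matrix.
#' @export
weights_from_scores <- function(X, T_scores) {
  X <- as.matrix(X)
  T_scores <- as.matrix(T_scores)
  stopifnot(nrow(X) == nrow(T_scores))
  MASS::ginv(X) %*% T_scores
}
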