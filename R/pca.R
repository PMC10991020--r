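#' Principal component analysis by singular value decomposition
#'
#' The closed-form least-squares solution to the rank-`R` decomposition
#' `X = T P' + E` with orthonormal loadings: scores `T = U_R S_R`, and both
#' the weights and the loadings equal to the right singular vectors `V_R`.
#' The numerical equality `W = P = V_R` is specific to ordinary PCA and is
#' exactly the property the sparse estimators in this package give up.
#'
#' @param X Numeric data matrix; columns are centered internally.
#' @param R Number of components, at most `min(nrow(X), ncol(X))`.
#' @return An object of class `spca_fit` with components ordered by variance
#'   accounted for and a deterministic sign convention (largest-magnitude
#'   entry of each right singular vector positive).
#' @examples
#' X <- center_columns(matrix(rnorm(60), 20, 3))
#' fit <- pca_svd(X, 2)
#' all.equal(fit$W, fit$P)
#' @export
pca_svd <- function(X, R) {
  X <- center_columns(X)
  if (R < 1 || R > min(dim(X))) {
    stop("`R` must be between 1 and min(nrow(X), ncol(X)) = ",
         min(dim(X)), call. = FALSE)
  }
  sv <- svd(X, nu = R, nv = R)
  V <- sv$v
  T_scores <- sv$u %*% diag(sv$d[seq_len(R)], R)
  recon <- sum((X - T_scores %*% t(V))^2)
  new_spca_fit("pca", X, W = V, P = V, T_scores = T_scores,
               loss = recon, recon = recon, loss_trajectory = recon,
               n_iter = 0L, converged = TRUE, init_label = "svd",
               nonzeros = nrow(V))
}
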