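# Constructor for fitted sparse PCA models. Applies the package-wide
# presentation conventions: components ordered by per-component VAF
# (descending, stable) and signs fixed so that the largest-magnitude
# coefficient of each column of the method's sparse block is positive.
new_spca_fit <- function(method, X, W, P, T_scores, loss, recon,
                         loss_trajectory, n_iter, converged,
                         init_label = "svd", lambda = NA_real_,
                         lambda2 = NA_real_, nonzeros = NA_integer_,
                         reseeded = 0L) {
  v <- vaf(X, T_scores, P)
  ord <- order(-v$per_comp)
  W <- W[, ord, drop = FALSE]
  P <- P[, ord, drop = FALSE]
  T_scores <- T_scores[, ord, drop = FALSE]
  per <- v$per_comp[ord]
  block <- if (method == "uslpca") P else W
  sgn <- component_signs(block)
  W <- sweep(W, 2L, sgn, "*")
  P <- sweep(P, 2L, sgn, "*")
  T_scores <- sweep(T_scores, 2L, sgn, "*")
  structure(
    list(method = method, W = W, P = P, T = T_scores,
         loss = loss, recon = recon, loss_trajectory = loss_trajectory,
         vaf_per_comp = per, vaf_total = v$total,
         n_iter = n_iter, converged = converged, init_label = init_label,
         lambda = lambda, lambda2 = lambda2, nonzeros = nonzeros,
         reseeded = reseeded),
    class = "spca_fit")
}

#' @export
print.spca_fit <- function(x, digits = 3, ...) {
  lab <- switch(x$method,
                pca = "PCA (SVD)",
                spca = "SPCA (sparse weights)",
                uslpca = "USLPCA (sparse loadings)")
  cat(lab, "fit:", ncol(x$W), "component(s),", nrow(x$W), "variable(s)\n")
  cat("  init:", x$init_label,
      " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  cat("  loss:", format(x$loss, digits = digits),
      " vaf per component:",
      paste(format(x$vaf_per_comp, digits = digits), collapse = ", "),
      " total:", format(x$vaf_total, digits = digits), "\n")
  invisible(x)
}

#' Objective value of a fitted sparse PCA model
#'
#' Recomputes the criterion each estimator minimizes, at the fitted
#' parameters. For the sparse-loadings method (and plain PCA) this is the
#' least-squares reconstruction loss `||X - T P'||_F^2`; for the
#' sparse-weights method it is the elastic-net objective
#' `||X - X W P'||_F^2 + lambda * sum_r ||w_r||_1 + lambda2 * sum_r ||w_r||_2^2`,
#' evaluated with the reporting penalty weights (which default to those stored
#' in the fit).
#'
#' @param fit An object of class `spca_fit`.
#' @param X The (centered) data matrix the model was fitted to.
#' @param lambda,lambda2 Reporting penalty weights for the sparse-weights
#'   objective; default to the values stored in the fit.
#' @return A single numeric value.
#' @export
objective_value <- function(fit, X, lambda = NULL, lambda2 = NULL) {
  stopifnot(inherits(fit, "spca_fit"))
  X <- as.matrix(X)
  if (fit$method == "spca") {
    if (is.null(lambda)) lambda <- fit$lambda
    if (is.null(lambda2)) lambda2 <- fit$lambda2
    recon <- sum((X - X %*% fit$W %*% t(fit$P))^2)
    recon + lambda * sum(abs(fit$W)) + lambda2 * sum(fit$W^2)
  } else {
    sum((X - fit$T %*% t(fit$P))^2)
  }
}
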