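#' Variance accounted for by a component model
#'
#' Total VAF is `1 - ||X - T P'||_F^2 / ||X||_F^2`; the per-component value
#' replaces the full reconstruction with the single rank-one term
#' `t_r p_r'`. Per-component values need not sum to the total unless the
#' scores are orthogonal.
#'
#' @param X Centered data matrix with `||X|| > 0`.
#' @param T_scores `I x R` score matrix.
#' @param P `J x R` loading matrix.
#' @return List with `per_comp` (length-`R` vector) and `total`.
#' @export
vaf <- function(X, T_scores, P) {
  X <- as.matrix(X)
  T_scores <- as.matrix(T_scores)
  P <- as.matrix(P)
  stopifnot(nrow(X) == nrow(T_scores), ncol(X) == nrow(P),
            ncol(T_scores) == ncol(P))
  ss <- sum(X^2)
  if (ss == 0) stop("`X` has zero sum of squares", call. = FALSE)
  total <- 1 - sum((X - tcrossprod(T_scores, P))^2) / ss
  per <- vapply(seq_len(ncol(P)), function(r) {
    1 - sum((X - tcrossprod(T_scores[, r], P[, r]))^2) / ss
  }, numeric(1))
  list(per_comp = per, total = total)
}

# all permutations of 1..n (n small; alignment is exhaustive by design)
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

col_congruence <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Align estimated components to a reference (permutation and signs)
#'
#' Component order and sign are arbitrary in any PCA-type model, so estimated
#' components must be matched to the reference before recovery statistics are
#' meaningful. This finds, by exhaustive search over all `R! * 2^R`
#' assignments, the column permutation and sign flips of `estimate` that
#' maximize the sum of absolute column-wise congruence (cosine) coefficients
#' with `reference`.
#'
#' @param reference,estimate Matrices with the same number of columns
#'   (`R <= 6`; the search is exhaustive).
#' @return List with `perm` (estimate column assigned to each reference
#'   column), `signs` (sign to apply to each permuted column), the `score`
#'   attained, and `aligned = estimate[, perm] %*% diag(signs)`.
#' @export
align_components <- function(reference, estimate) {
  reference <- as.matrix(reference)
  estimate <- as.matrix(estimate)
  R <- ncol(reference)
  stopifnot(ncol(estimate) == R, nrow(reference) == nrow(estimate))
  if (R > 6L) stop("exhaustive alignment supports at most 6 components",
                   call. = FALSE)
  phi <- matrix(0, R, R) # phi[i, j] = congruence(reference_i, estimate_j)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    phi[i, j] <- col_congruence(reference[, i], estimate[, j])
  }
  best <- NULL
  for (p in permutations_of(R)) {
    sc <- sum(abs(phi[cbind(seq_len(R), p)]))
    if (is.null(best) || sc > best$score) best <- list(perm = p, score = sc)
  }
  signs <- ifelse(phi[cbind(seq_len(R), best$perm)] < 0, -1, 1)
  aligned <- sweep(estimate[, best$perm, drop = FALSE], 2L, signs, "*")
  list(perm = best$perm, signs = signs, score = best$score, aligned = aligned)
}

#' Tucker congruence between score matrices
#'
#' The cosine between the vectorized score matrices,
#' \deqn{\phi = \frac{\mathrm{vec}(T^{true})' \mathrm{vec}(\hat T)}
#'  {\sqrt{(\mathrm{vec}(T^{true})'\mathrm{vec}(T^{true}))
#'         (\mathrm{vec}(\hat T)'\mathrm{vec}(\hat T))}}.}
#' Values of 0.85-0.94 are conventionally read as fair similarity of
#' components. Because sign and order of estimated components are arbitrary,
#' the estimate is aligned to the reference first (see
#' [align_components()]); the aligned statistic is non-negative in practice.
#'
#' @param T_true,T_est Score matrices of equal shape, neither all zero.
#' @param align Align `T_est` to `T_true` before computing the statistic.
#' @return A single number in `[-1, 1]`.
#' @export
tucker_phi <- function(T_true, T_est, align = TRUE) {
  T_true <- as.matrix(T_true)
  T_est <- as.matrix(T_est)
  stopifnot(all(dim(T_true) == dim(T_est)))
  if (all(T_true == 0) || all(T_est == 0)) {
    stop("scores must not be all zero", call. = FALSE)
  }
  if (align) T_est <- align_components(T_true, T_est)$aligned
  sum(T_true * T_est) / sqrt(sum(T_true^2) * sum(T_est^2))
}

#' Zero versus non-zero recovery rate
#'
#' Fraction of coefficient positions whose zero/non-zero status in the
#' estimate matches the true sparse structure, after aligning the estimated
#' columns to the true ones. The comparison is always made between the
#' quantity defined sparse by the data-generating model and the quantity the
#' method estimates sparse (weights for the sparse-weights method, loadings
#' for the sparse-loadings method), whatever their roles.
#'
#' @param true_sparse,est_sparse `J x R` coefficient matrices.
#' @param zero_tol Magnitudes at or below this are treated as zero. The
#'   estimators produce exact zeros, so the default is exact; a small
#'   positive value guards against serialization round-trips.
#' @return Fraction in `[0, 1]`.
#' @export
recovery_rate <- function(true_sparse, est_sparse, zero_tol = 0) {
  true_sparse <- as.matrix(true_sparse)
  est_sparse <- as.matrix(est_sparse)
  stopifnot(all(dim(true_sparse) == dim(est_sparse)))
  est_sparse <- align_components(true_sparse, est_sparse)$aligned
  mean((abs(true_sparse) > zero_tol) == (abs(est_sparse) > zero_tol))
}
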