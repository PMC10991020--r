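#' Mean-center the columns of a data matrix
#'
#' All estimators in this package assume variables with mean zero; this is the
#' canonical entry point that enforces it. The original column means (and,
#' optionally, standard deviations) are retained as attributes so that fitted
#' models can be mapped back to the raw scale.
#'
#' @param X A numeric matrix (observations in rows, variables in columns) or
#'   an object coercible to one. At least two rows are required.
#' @param standardize Also scale each column to unit standard deviation.
#'   Constant columns make standardization impossible and raise an error
#'   naming the offending column.
#' @return A numeric matrix with column means zero (within 1e-12), carrying
#'   attributes `col_means` and, if `standardize = TRUE`, `col_sds`.
#' @examples
#' X <- center_columns(matrix(c(1, 2, 3, 4, 6, 8), 3, 2))
#' colSums(X)
#' @export
center_columns <- function(X, standardize = FALSE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be a numeric matrix", call. = FALSE)
  if (nrow(X) < 2L) stop("`X` must have at least 2 rows", call. = FALSE)
  mu <- colMeans(X)
  X <- sweep(X, 2L, mu, "-")
  attr(X, "col_means") <- mu
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    bad <- which(sds < .Machine$double.eps^0.5)
    if (length(bad)) {
      nm <- colnames(X)[bad]
      if (is.null(nm)) nm <- as.character(bad)
      stop("cannot standardize constant column(s): ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
    X <- sweep(X, 2L, sds, "/")
    attr(X, "col_means") <- mu
    attr(X, "col_sds") <- sds
  }
  X
}

#' Orthonormal polar factor (orthogonal Procrustes solution)
#'
#' Returns the column-orthonormal matrix closest to `M`, i.e. the maximizer of
#' `trace(P' M)` over all `P` with `P'P = I`. Computed from the SVD
#' `M = U D V'` as `U V'`.
#'
#' @param M A numeric matrix with full column rank.
#' @return A matrix of the same shape with orthonormal columns.
#' @examples
#' M <- matrix(rnorm(10), 5, 2)
#' P <- procrustes_polar(M)
#' crossprod(P)
#' @export
procrustes_polar <- function(M) {
  M <- as.matrix(M)
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r < ncol(M)) {
    stop("`M` is rank deficient (rank ", r, " < ", ncol(M),
         " columns); the polar factor is not unique", call. = FALSE)
  }
  sv$u %*% t(sv$v)
}

# Polar factor that tolerates rank deficiency: used inside the alternating
# updates, where a rank-deficient intermediate only means the corresponding
# directions are arbitrary (any orthonormal completion attains the same loss).
polar_safe <- function(M) {
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

# Indices of the k largest |v|. Entries whose magnitude ties with the k-th
# largest (within a relative tolerance, to catch exact ties perturbed by
# floating point) are resolved in favour of the lowest variable index.
top_k_indices <- function(v, k, tie_tol = 1e-9) {
  a <- abs(v)
  if (k >= length(a)) return(seq_along(a))
  cutoff <- sort(a, decreasing = TRUE)[k]
  tol <- tie_tol * max(a, .Machine$double.xmin)
  sure <- which(a > cutoff + tol)
  tied <- setdiff(which(a >= cutoff - tol), sure)
  c(sure, tied[seq_len(k - length(sure))])
}

# Keep the k largest-magnitude entries per column, zero the rest.
hard_threshold_columns <- function(M, k, tie_tol = 1e-9) {
  out <- matrix(0, nrow(M), ncol(M))
  for (r in seq_len(ncol(M))) {
    keep <- top_k_indices(M[, r], k, tie_tol)
    out[keep, r] <- M[keep, r]
  }
  dimnames(out) <- dimnames(M)
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fix component signs so that each column's largest-magnitude coefficient in
# `block` is positive (ties resolved at the lowest index). Returns the sign
# vector to apply to all blocks of the fit.
component_signs <- function(block, tie_tol = 1e-9) {
  vapply(seq_len(ncol(block)), function(r) {
    v <- block[, r]
    a <- abs(v)
    m <- max(a)
    if (m == 0) return(1)
    j <- which(a >= m - tie_tol * m)[1L]
    if (v[j] < 0) -1 else 1
  }, numeric(1))
}
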