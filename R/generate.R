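#' Configuration for the synthetic data-generating models
#'
#' Describes one dataset from one of the three data-generating models (DGMs)
#' used to assess the sparse estimators: `"spiked_covariance"` (sparse,
#' orthonormal right singular vectors, so weights and loadings coincide),
#' `"sparse_loadings"` (`X = T P' + E` with sparse `P`) and
#' `"sparse_weights"` (`X = X W P' + E` with sparse `W`). Sparsity is the
#' fraction of zero entries per coefficient column; `pev` is the proportion
#' of error variance, the share of the total sum of squares contributed by
#' the error part.
#'
#' @param model One of `"spiked_covariance"`, `"sparse_loadings"`,
#'   `"sparse_weights"`.
#' @param I,J Numbers of observations and variables.
#' @param R Number of components (default 2, as in the simulation design).
#' @param sparsity Fraction of zeros per coefficient column, in `[0, 1)`;
#'   the per-column support size is `k = round((1 - sparsity) * J) >= 1`.
#' @param pev Proportion of error variance in `[0, 1)`.
#' @param correlated_init Draw the rows of the initial matrix from a
#'   multivariate normal with AR(1) correlation `ar_rho^|i-j|` instead of the
#'   identity.
#' @param ar_rho AR(1) correlation parameter (only used when
#'   `correlated_init` is `TRUE`).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return An object of class `dgm_config`.
#' @export
dgm_config <- function(model = c("spiked_covariance", "sparse_loadings",
                                 "sparse_weights"),
                       I, J, R = 2L, sparsity, pev,
                       correlated_init = FALSE, ar_rho = 0.5, seed = 1L) {
  model <- match.arg(model)
  I <- as.integer(I); J <- as.integer(J); R <- as.integer(R)
  if (R < 1L || R > min(I, J)) stop("need 1 <= R <= min(I, J)", call. = FALSE)
  if (I <= R) stop("need I > R (the scores must span R directions)", call. = FALSE)
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must be in [0, 1)", call. = FALSE)
  if (pev < 0 || pev >= 1) stop("`pev` must be in [0, 1)", call. = FALSE)
  k <- as.integer(round((1 - sparsity) * J))
  if (k < 1L) stop("sparsity leaves no non-zero entries per column", call. = FALSE)
  if (model != "sparse_weights" && k * R > J) {
    stop("disjoint supports infeasible: round((1 - sparsity) * J) * R > J",
         call. = FALSE)
  }
  structure(list(model = model, I = I, J = J, R = R, sparsity = sparsity,
                 pev = pev, k = k, correlated_init = isTRUE(correlated_init),
                 ar_rho = ar_rho, seed = as.integer(seed)),
            class = "dgm_config")
}

#' Sparse column-orthonormal matrix with disjoint supports
#'
#' Builds a `J x R` matrix whose columns are unit-norm, mutually orthogonal
#' and have exactly `k = round((1 - sparsity) * J)` non-zero entries each.
#' Supports of distinct columns are disjoint (chosen uniformly at random), so
#' orthogonality is exact by construction.
#'
#' By default the non-zero entries have equal magnitude `1/sqrt(k)` with
#' independent random signs, as in the classical single-spike construction of
#' the spiked-covariance literature. This keeps every true coefficient
#' bounded away from zero, which is what makes perfect zero/non-zero recovery
#' attainable on noiseless data; with `values = "uniform"` the entries are
#' instead drawn U(-1, 1) and normalized, in which case some true
#' coefficients can be arbitrarily small and no method can tell them from
#' zero. Uses the current RNG state; seed with `set.seed()` (or generate
#' through [generate_dataset()], which seeds for you).
#'
#' @param J,R Dimensions.
#' @param sparsity Fraction of zeros per column, in `[0, 1)`.
#' @param values `"equal"` for equal-magnitude random-sign entries,
#'   `"uniform"` for U(-1, 1) entries (column-normalized).
#' @return A `J x R` matrix `V` with `crossprod(V)` equal to the identity.
#' @export
make_sparse_orthonormal <- function(J, R, sparsity,
                                    values = c("equal", "uniform")) {
  values <- match.arg(values)
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must be in [0, 1)", call. = FALSE)
  k <- as.integer(round((1 - sparsity) * J))
  if (k < 1L) stop("sparsity leaves no non-zero entries per column", call. = FALSE)
  if (k * R > J) {
    stop("cannot place ", R, " disjoint supports of size ", k, " in ", J,
         " variables", call. = FALSE)
  }
  slots <- sample.int(J, k * R)
  V <- matrix(0, J, R)
  for (r in seq_len(R)) {
    idx <- slots[((r - 1L) * k + 1L):(r * k)]
    if (values == "equal") {
      V[idx, r] <- sample(c(-1, 1), k, replace = TRUE) / sqrt(k)
    } else {
      repeat {
        vals <- stats::runif(k, -1, 1)
        nrm <- sqrt(sum(vals^2))
        if (nrm > 1e-8) break
      }
      V[idx, r] <- vals / nrm
    }
  }
  V
}

#' Scale an error matrix to realize a proportion of error variance
#'
#' Rescales `E_raw` so that `||E||_F^2 / (||X_model||_F^2 + ||E||_F^2)`
#' equals `pev` exactly. Provided the error is orthogonal to the model part
#' (as the generators guarantee), this is also the error share of the final
#' data `X = X_model + E`.
#'
#' @param X_model Model part of the data.
#' @param E_raw Unscaled error matrix; must be non-zero unless `pev = 0`.
#' @param pev Proportion of error variance in `[0, 1)`.
#' @return The scaled error matrix (the zero matrix when `pev = 0`).
#' @export
scale_error_to_pev <- function(X_model, E_raw, pev) {
  if (pev < 0 || pev >= 1) stop("`pev` must be in [0, 1)", call. = FALSE)
  X_model <- as.matrix(X_model)
  E_raw <- as.matrix(E_raw)
  stopifnot(all(dim(X_model) == dim(E_raw)))
  if (pev == 0) return(matrix(0, nrow(E_raw), ncol(E_raw)))
  ssE <- sum(E_raw^2)
  if (ssE == 0) stop("`E_raw` is zero but `pev` > 0", call. = FALSE)
  E_raw * sqrt(pev / (1 - pev) * sum(X_model^2) / ssE)
}

# Orthonormal complement of the columns of V (J x (J - ncol(V))), via the
# full QR decomposition.
orthonormal_complement <- function(V) {
  J <- nrow(V)
  R <- ncol(V)
  qr.Q(qr(V), complete = TRUE)[, (R + 1L):J, drop = FALSE]
}

#' Generate a dataset with known sparse structure
#'
#' Draws a dataset under the configured data-generating model and returns it
#' together with the ground truth the evaluation statistics need. The common
#' skeleton: an `I x J` initial matrix with i.i.d. standard-normal rows
#' (optionally AR(1)-correlated) is column-centered and decomposed by SVD;
#' its leading singular values set the signal scale and its trailing singular
#' triplets furnish the error part, so the model part and the error part are
#' exactly uncorrelated (orthogonal columns). The error is then scaled so the
#' realized proportion of error variance matches `pev` exactly, and the final
#' data `X = X_model + E` is column-centered by construction.
#'
#' Model specifics:
#' \describe{
#'   \item{spiked covariance}{`X_model = U_R S_R V_R'` with sparse
#'     orthonormal `V_R` from [make_sparse_orthonormal()]; the true sparse
#'     structure `V_R` serves as both weights and loadings, and the true
#'     scores are `U_R S_R` (so `X V_R` reproduces them exactly at
#'     `pev = 0`). The error lives in an orthonormal complement of `V_R`.}
#'   \item{sparse loadings}{same construction, reparameterized as
#'     orthonormal scores `T = U_R` with sparse loadings `P = V_R S_R`.}
#'   \item{sparse weights}{a sparse `J x R` weights matrix `W` (k non-zeros
#'     per column at uniformly random positions, values U(-1, 1)) defines
#'     scores `T = X_init W`; the non-sparse loadings are the orthonormal
#'     Procrustes solution `P = polar(X_init' X_init W)` and
#'     `X_model = T P'`. The error is built from the trailing singular
#'     triplets of `X_init` projected onto the orthogonal complement of the
#'     column space of `X_model`.}
#' }
#'
#' @param config A [dgm_config()].
#' @return An object of class `ground_truth`: list with `X`, `X_model`, `E`,
#'   `true_sparse` (`V_R`, `P_R` or `W_R` depending on the model),
#'   `true_scores`, `k` and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "dgm_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  I <- config$I; J <- config$J; R <- config$R
  k <- config$k; pev <- config$pev

  X_init <- matrix(stats::rnorm(I * J), I, J)
  if (config$correlated_init) {
    Sigma <- config$ar_rho^abs(outer(seq_len(J), seq_len(J), "-"))
    X_init <- X_init %*% chol(Sigma)
  }
  # centering here makes every derived column (scores, error directions)
  # mean-zero, so the final X is centered and the PEV bookkeeping is exact
  X_init <- center_columns(X_init)
  sv <- svd(X_init)
  m <- min(I, J)
  if (sum(sv$d > 1e-12 * sv$d[1]) <= R) {
    stop("initial matrix has rank <= R; increase I", call. = FALSE)
  }
  U_R <- sv$u[, seq_len(R), drop = FALSE]
  S_R <- sv$d[seq_len(R)]
  rest <- (R + 1L):m
  n_rest <- length(rest)

  if (config$model %in% c("spiked_covariance", "sparse_loadings")) {
    V_R <- make_sparse_orthonormal(J, R, config$sparsity)
    X_model <- U_R %*% (S_R * t(V_R))
    if (config$model == "spiked_covariance") {
      true_sparse <- V_R
      true_scores <- U_R %*% diag(S_R, R)
    } else {
      true_sparse <- V_R %*% diag(S_R, R)
      true_scores <- U_R
    }
    if (pev > 0) {
      V_comp <- orthonormal_complement(V_R)[, seq_len(n_rest), drop = FALSE]
      E_raw <- sv$u[, rest, drop = FALSE] %*% (sv$d[rest] * t(V_comp))
    } else {
      E_raw <- matrix(0, I, J)
    }
  } else {
    W_R <- matrix(0, J, R)
    for (r in seq_len(R)) {
      W_R[sample.int(J, k), r] <- stats::runif(k, -1, 1)
    }
    T_scores <- X_init %*% W_R
    P_R <- procrustes_polar(crossprod(X_init) %*% W_R)
    X_model <- tcrossprod(T_scores, P_R)
    true_sparse <- W_R
    true_scores <- T_scores
    if (pev > 0) {
      E_raw <- sv$u[, rest, drop = FALSE] %*% (sv$d[rest] * t(sv$v[, rest, drop = FALSE]))
      # project onto the complement of the column space of X_model so the
      # error is uncorrelated with the model part
      Q <- qr.Q(qr(T_scores))
      E_raw <- E_raw - Q %*% crossprod(Q, E_raw)
    } else {
      E_raw <- matrix(0, I, J)
    }
  }

  E <- scale_error_to_pev(X_model, E_raw, pev)
  X <- center_columns(X_model + E)
  structure(list(X = X, X_model = X_model, E = E,
                 true_sparse = true_sparse, true_scores = true_scores,
                 k = k, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cfg <- x$config
  cat("ground truth:", cfg$model, sprintf("(%d x %d, R = %d)", cfg$I, cfg$J,
                                          cfg$R), "\n")
  cat("  sparsity:", cfg$sparsity, "(", x$k, "non-zeros/column )",
      " pev:", cfg$pev, " seed:", cfg$seed, "\n")
  invisible(x)
}
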