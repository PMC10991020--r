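#' Initialization strategy for the alternating sparse PCA estimators
#'
#' Both sparse estimators are non-convex and converge to local optima, so the
#' choice of starting values matters. Two protocols are supported: the
#' conventional SVD-based start (the right singular vectors `V_R` of the
#' data) and a multistart protocol that adds random start matrices with
#' entries drawn from U(-1, 1). The simulation protocol in this package uses
#' the SVD start plus 19 random starts; the toy protocol uses 100 random
#' starts without the SVD start. Both are expressible here.
#'
#' @param kind `"svd"` for the single SVD-based start, `"multistart"` for
#'   random starts (optionally including the SVD start).
#' @param n_random_starts Number of random starts (multistart only).
#' @param include_svd_start Include `V_R` as an additional start.
#' @param seed Integer seed from which the per-start random streams are
#'   derived (start `i` uses `seed + i`), so runs are reproducible and
#'   individual starts can be replayed in isolation.
#' @return An object of class `init_strategy`.
#' @export
init_strategy <- function(kind = c("svd", "multistart"),
                          n_random_starts = 19L,
                          include_svd_start = TRUE,
                          seed = 1L) {
  kind <- match.arg(kind)
  n_random_starts <- as.integer(n_random_starts)
  if (kind == "multistart" && n_random_starts < 1L) {
    stop("multistart requires at least one random start", call. = FALSE)
  }
  structure(list(kind = kind,
                 n_random_starts = n_random_starts,
                 include_svd_start = isTRUE(include_svd_start),
                 seed = as.integer(seed)),
            class = "init_strategy")
}

#' Generate the initial loading matrices for a strategy
#'
#' Both estimators are initialized through the loadings block (for the
#' SVD-based start this is the canonical choice, since `V_R` initializes
#' either method's first half-step).
#'
#' @param X Centered data matrix.
#' @param R Number of components.
#' @param strategy An [init_strategy()].
#' @return A named list of `J x R` start matrices; the SVD start (if
#'   present) is named `"svd"`, random starts `"random1"`, `"random2"`, ...
#' @export
initial_values <- function(X, R, strategy) {
  stopifnot(inherits(strategy, "init_strategy"))
  X <- as.matrix(X)
  J <- ncol(X)
  if (R > min(dim(X))) stop("`R` must be at most min(I, J)", call. = FALSE)
  svd_start <- svd(X, nu = 0, nv = R)$v
  if (strategy$kind == "svd") return(list(svd = svd_start))
  starts <- list()
  if (strategy$include_svd_start) starts$svd <- svd_start
  for (i in seq_len(strategy$n_random_starts)) {
    starts[[paste0("random", i)]] <-
      with_seed(strategy$seed + i, matrix(stats::runif(J * R, -1, 1), J, R))
  }
  starts
}

#' Fit from multiple starting values and keep the best solution
#'
#' Runs the chosen estimator once per start matrix and accepts the solution
#' with the lowest least-squares reconstruction loss. Reconstruction losses
#' that tie within a relative tolerance of 1e-8 are resolved by the full
#' reported objective (for the sparse-weights method this includes the
#' elastic-net penalty), then by start order, so the selection is
#' deterministic.
#'
#' @param X Data matrix; columns are centered internally.
#' @param method `"spca"` or `"uslpca"`.
#' @param R Number of components.
#' @param nonzeros Per-component cardinality passed to the estimator.
#' @param strategy An [init_strategy()]; defaults to the simulation protocol
#'   (SVD start + 19 random starts).
#' @param ... Further arguments passed to [fit_spca()] or [fit_uslpca()].
#' @return The selected `spca_fit`, with a data frame of per-start
#'   diagnostics (start label, reconstruction loss, objective, convergence)
#'   attached as `fit$starts`.
#' @export
multistart_fit <- function(X, method = c("spca", "uslpca"), R, nonzeros,
                           strategy = init_strategy("multistart"), ...) {
  method <- match.arg(method)
  X <- center_columns(X)
  starts <- initial_values(X, R, strategy)
  fitter <- switch(method, spca = fit_spca, uslpca = fit_uslpca)
  fits <- vector("list", length(starts))
  errors <- character(0)
  for (i in seq_along(starts)) {
    fits[[i]] <- tryCatch(
      fitter(X, R = R, nonzeros = nonzeros, P_init = starts[[i]],
             init_label = names(starts)[i], ...),
      error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      errors <- c(errors, paste0(names(starts)[i], ": ",
                                 conditionMessage(fits[[i]])))
    }
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    stop("all ", length(starts), " starts failed: ",
         paste(errors, collapse = "; "), call. = FALSE)
  }
  fits <- fits[ok]
  recon <- vapply(fits, `[[`, numeric(1), "recon")
  obj <- vapply(fits, `[[`, numeric(1), "loss")
  tied <- which(recon <= min(recon) + 1e-8 * max(1, min(recon)))
  sel <- tied[which.min(obj[tied])]
  out <- fits[[sel]]
  out$init_label <- paste0("multistart[", out$init_label, "]")
  out$starts <- data.frame(
    start = vapply(fits, `[[`, character(1), "init_label"),
    recon = recon,
    objective = obj,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    selected = seq_along(fits) == sel)
  if (length(errors)) out$start_errors <- errors
  out
}
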