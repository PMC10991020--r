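#' Reproduce the toy-example comparison table
#'
#' Runs the five analyses of the toy dataset — PCA, the sparse-weights
#' estimator with SVD-based and multistart initialization, and the
#' sparse-loadings estimator with both initializations — with one coefficient
#' per component constrained to zero (the true sparsity) and 100 random
#' U(-1, 1) starts for the multistart variants. The sparse-weights objective
#' is reported with lasso weight `lambda = 2` and no ridge.
#'
#' @param n_random_starts Number of random starts for the multistart rows.
#' @param include_svd_start Whether the multistart protocol also includes the
#'   SVD start (the toy protocol uses random starts only).
#' @param seed Seed for the random starts.
#' @param exact Analyze the exact rank-two reconstruction of the toy data
#'   (default) rather than the two-decimal printed matrix; see
#'   [toy_dataset()] for why the exact form is the faithful choice.
#' @param digits Rounding applied to the table columns (the fits retain full
#'   precision).
#' @return List with `table` (one row per method: loss, per-component and
#'   total VAF) and `fits` (the five `spca_fit` objects).
#' @export
reproduce_toy_table <- function(n_random_starts = 100L,
                                include_svd_start = FALSE,
                                seed = 1L, exact = TRUE, digits = 2) {
  toy <- toy_dataset()
  X <- if (exact) toy$X_exact else toy$X
  k <- 2L  # one zero coefficient per component, as in the true loadings
  multi <- init_strategy("multistart", n_random_starts = n_random_starts,
                         include_svd_start = include_svd_start, seed = seed)
  fits <- list(
    pca = pca_svd(X, 2L),
    spca_svd = fit_spca(X, 2L, nonzeros = k, lambda = 2, lambda2 = 0),
    spca_multi = multistart_fit(X, "spca", 2L, nonzeros = k,
                                strategy = multi, lambda = 2, lambda2 = 0),
    uslpca_svd = fit_uslpca(X, 2L, nonzeros = k),
    uslpca_multi = multistart_fit(X, "uslpca", 2L, nonzeros = k,
                                  strategy = multi))
  tab <- data.frame(
    method = c("PCA", "SPCA-svd", "SPCA-multi", "USLPCA-svd", "USLPCA-multi"),
    loss = vapply(fits, `[[`, numeric(1), "loss"),
    vaf_1 = vapply(fits, function(f) f$vaf_per_comp[1], numeric(1)),
    vaf_2 = vapply(fits, function(f) f$vaf_per_comp[2], numeric(1)),
    vaf_total = vapply(fits, `[[`, numeric(1), "vaf_total"),
    row.names = NULL)
  tab[-1] <- round(tab[-1], digits)
  list(table = tab, fits = fits)
}

#' Factorial design for the simulation study
#'
#' Full crossing of data-generating model, data dimensions, coefficient
#' sparsity and proportion of error variance, with a number of replicate
#' datasets per condition. The default arguments give the full published
#' design (3 models x 2 dimensions x 2 sparsity levels x 3 PEV levels = 36
#' conditions, 50 replicates); pass smaller values for a desk-scale run —
#' any subset of levels keeps the full factorial crossing.
#'
#' @param models Character vector of DGM names.
#' @param dims List of `c(I, J)` pairs.
#' @param sparsity_levels,pev_levels Numeric vectors of factor levels.
#' @param replicates Datasets per condition.
#' @param R Number of components.
#' @param n_random_starts,include_svd_start Multistart protocol for the
#'   `-multi` analysis methods (the simulation protocol is the SVD start
#'   plus 19 random starts).
#' @param lambda2 Ridge weight for the sparse-weights estimator (a small
#'   positive default keeps the weight update stable when `J > I`).
#' @param master_seed Seed from which every per-dataset and per-start stream
#'   is derived; equal seeds reproduce every record.
#' @return An object of class `study_design`.
#' @export
study_design <- function(models = c("spiked_covariance", "sparse_loadings",
                                    "sparse_weights"),
                         dims = list(c(100L, 50L), c(100L, 500L)),
                         sparsity_levels = c(0.9, 0.5),
                         pev_levels = c(0, 0.1, 0.5),
                         replicates = 50L,
                         R = 2L,
                         n_random_starts = 19L,
                         include_svd_start = TRUE,
                         lambda2 = 1e-6,
                         master_seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (!length(dims) || !all(vapply(dims, length, integer(1)) == 2L)) {
    stop("`dims` must be a list of c(I, J) pairs", call. = FALSE)
  }
  structure(list(models = models, dims = dims,
                 sparsity_levels = sparsity_levels, pev_levels = pev_levels,
                 replicates = as.integer(replicates), R = as.integer(R),
                 n_random_starts = as.integer(n_random_starts),
                 include_svd_start = isTRUE(include_svd_start),
                 lambda2 = lambda2,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Enumerate the conditions of a design
#'
#' @param design A [study_design()].
#' @return Data frame with one row per condition (model, I, J, sparsity,
#'   pev), in a deterministic order.
#' @export
design_conditions <- function(design) {
  stopifnot(inherits(design, "study_design"))
  dims <- do.call(rbind, design$dims)
  grid <- expand.grid(dim_idx = seq_len(nrow(dims)),
                      model = design$models,
                      sparsity = design$sparsity_levels,
                      pev = design$pev_levels,
                      stringsAsFactors = FALSE)
  data.frame(condition = seq_len(nrow(grid)),
             model = grid$model,
             I = dims[grid$dim_idx, 1],
             J = dims[grid$dim_idx, 2],
             sparsity = grid$sparsity,
             pev = grid$pev)
}

# deterministic per-(condition, replicate, stream) seed below 2^31
derive_seed <- function(master_seed, condition, replicate, stream = 0L) {
  base <- (as.double(master_seed) * 1000003 + condition * 104729 +
             replicate * 7919 + stream * 433) %% 2147483629
  as.integer(base) + 1L
}

#' Run a simulation design
#'
#' For every condition and replicate: generate a dataset with a derived seed,
#' analyze it with the four methods (sparse-weights and sparse-loadings
#' estimators, each with SVD-based and multistart initialization) with the
#' true per-component cardinality supplied as input, and score each fit
#' against the ground truth (zero/non-zero recovery of the sparse block,
#' Tucker congruence of the component scores, variance accounted for).
#' Individual fit failures are recorded in the output row (`error` column)
#' and never abort the grid. The run is fully determined by the design's
#' `master_seed`.
#'
#' @param design A [study_design()].
#' @param verbose Print one line per condition.
#' @return Data frame of class `eval_records`: one row per condition x
#'   replicate x method with columns `model, I, J, R, sparsity, pev,
#'   replicate, method, init, recovery_rate, phi, vaf_total, vaf_1, loss,
#'   recon` (least-squares reconstruction loss, the multistart selection
#'   criterion), `converged, error`.
#' @export
run_design <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  conds <- design_conditions(design)
  rows <- vector("list", nrow(conds) * design$replicates * 4L)
  n <- 0L
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    if (verbose) {
      message(sprintf("condition %d/%d: %s I=%d J=%d sparsity=%.2f pev=%.2f",
                      ci, nrow(conds), cond$model, cond$I, cond$J,
                      cond$sparsity, cond$pev))
    }
    for (rep_i in seq_len(design$replicates)) {
      cfg <- dgm_config(cond$model, I = cond$I, J = cond$J, R = design$R,
                        sparsity = cond$sparsity, pev = cond$pev,
                        seed = derive_seed(design$master_seed, ci, rep_i))
      truth <- generate_dataset(cfg)
      for (method in c("spca", "uslpca")) {
        for (init in c("svd", "multi")) {
          n <- n + 1L
          rows[[n]] <- eval_one_fit(truth, method, init, design,
                                    cond, rep_i, ci)
        }
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(n)])
  class(out) <- c("eval_records", class(out))
  out
}

eval_one_fit <- function(truth, method, init, design, cond, rep_i, ci) {
  base <- data.frame(model = cond$model, I = cond$I, J = cond$J,
                     R = design$R, sparsity = cond$sparsity, pev = cond$pev,
                     replicate = rep_i,
                     method = paste0(toupper(method), "-", init),
                     init = init, stringsAsFactors = FALSE)
  fit <- tryCatch({
    if (init == "svd") {
      if (method == "spca") {
        fit_spca(truth$X, design$R, nonzeros = truth$k,
                 lambda2 = design$lambda2)
      } else {
        fit_uslpca(truth$X, design$R, nonzeros = truth$k)
      }
    } else {
      strat <- init_strategy("multistart",
                             n_random_starts = design$n_random_starts,
                             include_svd_start = design$include_svd_start,
                             seed = derive_seed(design$master_seed, ci,
                                                rep_i, stream = 1L))
      if (method == "spca") {
        multistart_fit(truth$X, "spca", design$R, nonzeros = truth$k,
                       strategy = strat, lambda2 = design$lambda2)
      } else {
        multistart_fit(truth$X, "uslpca", design$R, nonzeros = truth$k,
                       strategy = strat)
      }
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(cbind(base, data.frame(recovery_rate = NA_real_, phi = NA_real_,
                                  vaf_total = NA_real_, vaf_1 = NA_real_,
                                  loss = NA_real_, recon = NA_real_,
                                  converged = NA,
                                  error = conditionMessage(fit))))
  }
  sparse_block <- if (method == "spca") fit$W else fit$P
  cbind(base, data.frame(
    recovery_rate = recovery_rate(truth$true_sparse, sparse_block),
    phi = tucker_phi(truth$true_scores, fit$T),
    vaf_total = fit$vaf_total,
    vaf_1 = fit$vaf_per_comp[1],
    loss = fit$loss,
    recon = fit$recon,
    converged = fit$converged,
    error = NA_character_))
}

#' Summarize evaluation records per condition and method
#'
#' @param records Output of [run_design()].
#' @param metrics Metric columns to summarize.
#' @return Long-format data frame keyed by condition x method x metric with
#'   the median and quartiles over replicates.
#' @export
summarize_records <- function(records,
                              metrics = c("recovery_rate", "phi",
                                          "vaf_total")) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  keys <- c("model", "I", "J", "sparsity", "pev", "method")
  keys <- keys[keys %in% names(records)]
  out <- list()
  grp <- interaction(records[keys], drop = TRUE)
  for (metric in metrics) {
    stopifnot(metric %in% names(records))
    for (g in levels(grp)) {
      sub <- records[grp == g, , drop = FALSE]
      v <- sub[[metric]]
      v <- v[!is.na(v)]
      qs <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                           type = 7)
            else rep(NA_real_, 3)
      out[[length(out) + 1L]] <- cbind(
        sub[1L, keys, drop = FALSE],
        data.frame(metric = metric, n = length(v),
                   q1 = qs[1], median = qs[2], q3 = qs[3]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
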