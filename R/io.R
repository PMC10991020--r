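#' Read a numeric data matrix from a delimited text file
#'
#' Reads a rectangular numeric table, mean-centers each column (all
#' estimators assume centered variables) and optionally standardizes to unit
#' variance. Row and column labels, when present, are retained as dimnames;
#' the original column means/sds are kept as attributes.
#'
#' @param path File path.
#' @param delimiter Field separator (default comma).
#' @param header Does the first row hold column names?
#' @param row_names Does the first column hold row names?
#' @param standardize Scale columns to unit variance (constant columns raise
#'   an error naming the column).
#' @return A centered numeric matrix (see [center_columns()]).
#' @export
read_matrix <- function(path, delimiter = ",", header = FALSE,
                        row_names = FALSE, standardize = FALSE) {
  df <- utils::read.table(path, sep = delimiter, header = header,
                          row.names = if (row_names) 1L else NULL,
                          check.names = FALSE, colClasses = NA)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric values in column(s) ",
         paste(names(df)[bad], collapse = ", "), " of ", path, call. = FALSE)
  }
  center_columns(as.matrix(df), standardize = standardize)
}

#' Write a numeric matrix as delimited text
#'
#' @param X Numeric matrix.
#' @param path Output path.
#' @param delimiter Field separator.
#' @param header Write column names as a first row.
#' @param row_names Write row names as a first column.
#' @export
write_matrix <- function(X, path, delimiter = ",", header = FALSE,
                         row_names = FALSE) {
  utils::write.table(as.matrix(X), path, sep = delimiter,
                     col.names = header, row.names = row_names,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a generated dataset with its ground truth
#'
#' Writes/reads the full [generate_dataset()] output as a single JSON
#' container with keys `X`, `X_model`, `E`, `true_sparse`, `true_scores` and
#' `config`, at full double precision.
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `save_ground_truth()` returns the path; `load_ground_truth()` the
#'   restored `ground_truth` object.
#' @export
save_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(X = truth$X, X_model = truth$X_model, E = truth$E,
                  true_sparse = truth$true_sparse,
                  true_scores = truth$true_scores, k = truth$k,
                  config = unclass(truth$config))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_ground_truth
#' @export
load_ground_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- dgm_config(cfg$model, I = cfg$I, J = cfg$J, R = cfg$R,
                       sparsity = cfg$sparsity, pev = cfg$pev,
                       correlated_init = cfg$correlated_init,
                       ar_rho = cfg$ar_rho, seed = cfg$seed)
  structure(list(X = payload$X, X_model = payload$X_model, E = payload$E,
                 true_sparse = payload$true_sparse,
                 true_scores = payload$true_scores,
                 k = payload$k, config = config),
            class = "ground_truth")
}

#' Serialize a fitted model to JSON
#'
#' @param fit An `spca_fit`.
#' @param path Output path.
#' @export
save_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spca_fit"))
  payload <- unclass(fit)
  payload$starts <- NULL
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Save or load a simulation design as YAML
#'
#' The design round-trips losslessly: `load_design(save_design(d, f))`
#' reproduces `d` field for field, so a run configuration can live next to
#' its results.
#'
#' @param design A [study_design()].
#' @param path YAML file path.
#' @return `save_design()` the path, invisibly; `load_design()` the restored
#'   `study_design`.
#' @export
save_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  payload <- unclass(design)
  payload$dims <- lapply(payload$dims, as.integer)
  yaml::write_yaml(payload, path, precision = 15L)
  invisible(path)
}

#' @rdname save_design
#' @export
load_design <- function(path) {
  p <- yaml::read_yaml(path)
  study_design(models = p$models,
               dims = lapply(p$dims, as.integer),
               sparsity_levels = as.numeric(p$sparsity_levels),
               pev_levels = as.numeric(p$pev_levels),
               replicates = p$replicates,
               R = p$R,
               n_random_starts = p$n_random_starts,
               include_svd_start = p$include_svd_start,
               lambda2 = p$lambda2,
               master_seed = p$master_seed)
}

#' Screen variables by one-way ANOVA against a grouping
#'
#' For each column of `X`, computes the one-way ANOVA F test of mean
#' differences across groups, and returns (a) the columns with p below
#' `keep_p_below` and (b) a seeded random sample of `n_redundant` columns
#' with p above `redundant_p_above` — the screening-plus-redundant-probes
#' construction used to assemble a matrix in which only a known subset of
#' variables carries group signal.
#'
#' @param X Numeric matrix (observations x variables).
#' @param groups Group labels, one per row; at least two groups with at
#'   least two members each.
#' @param keep_p_below Inclusion threshold for informative columns.
#' @param redundant_p_above Eligibility threshold for redundant columns.
#' @param n_redundant How many redundant columns to sample (error if fewer
#'   are eligible).
#' @param seed Seed for the redundant sample.
#' @return List with `keep`, `redundant`, `selected` (their union, sorted)
#'   and the per-column `p_value` and `f_statistic`.
#' @export
anova_screen <- function(X, groups, keep_p_below = 0.05,
                         redundant_p_above = 0.5, n_redundant = 0L,
                         seed = 1L) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) stop("one group label per row", call. = FALSE)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 members", call. = FALSE)
  n <- nrow(X)
  g <- nlevels(groups)
  grand <- colMeans(X)
  ss_between <- numeric(ncol(X))
  ss_within <- numeric(ncol(X))
  for (lev in levels(groups)) {
    sub <- X[groups == lev, , drop = FALSE]
    mu <- colMeans(sub)
    ss_between <- ss_between + nrow(sub) * (mu - grand)^2
    ss_within <- ss_within + colSums(sweep(sub, 2L, mu, "-")^2)
  }
  f_stat <- (ss_between / (g - 1)) / (ss_within / (n - g))
  p <- stats::pf(f_stat, g - 1, n - g, lower.tail = FALSE)
  keep <- which(p < keep_p_below)
  eligible <- which(p > redundant_p_above)
  redundant <- integer(0)
  if (n_redundant > 0L) {
    if (length(eligible) < n_redundant) {
      stop("requested ", n_redundant, " redundant columns but only ",
           length(eligible), " have p > ", redundant_p_above, call. = FALSE)
    }
    redundant <- sort(with_seed(seed, sample(eligible, n_redundant)))
  }
  list(keep = keep, redundant = redundant,
       selected = sort(union(keep, redundant)),
       p_value = p, f_statistic = f_stat)
}
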