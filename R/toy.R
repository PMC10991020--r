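#' The 5 x 3 rank-two toy dataset
#'
#' A small dataset generated from a 2-component model with orthonormal scores
#' and sparse loadings (one zero per loading column), on which ordinary PCA,
#' the sparse-weights and the sparse-loadings estimators all return visibly
#' different weights and loadings. `X`, `T` and `P` are the published values,
#' printed to two decimals, with column sums of `X` equal to zero.
#'
#' Because the printed matrices are rounded, the list also carries an exact
#' rank-two reconstruction: `P_exact` has entries `2` and `sqrt(2)`, `T_exact`
#' is the orthonormal polar factor of the centered printed scores, and
#' `X_exact = T_exact %*% t(P_exact)`. The reconstruction is column-centered,
#' has squared Frobenius norm exactly 12, differs from the printed `X` by
#' less than 0.012 per entry, and satisfies `X'X = P P'` exactly — which
#' matters: the local-optimum structure of the sparse-loadings method on this
#' dataset hinges on an exact magnitude tie in the first right singular
#' vector (`(1/2, sqrt(2)/2, 1/2)`) that two-decimal rounding breaks. The
#' analysis protocol ([reproduce_toy_table()]) therefore runs on the exact
#' reconstruction.
#'
#' @return List with the printed `X` (5 x 3), `T` (5 x 2), `P` (3 x 2) and
#'   the exact counterparts `X_exact`, `T_exact`, `P_exact`.
#' @examples
#' toy <- toy_dataset()
#' colSums(toy$X)
#' crossprod(toy$T)  # identity within printed rounding
#' @export
toy_dataset <- function() {
  X <- matrix(c(0.63, 0.52, 0.11,
                -1.56, -0.88, 0.30,
                0.04, 0.83, 1.14,
                1.07, 0.80, 0.06,
                -0.18, -1.27, -1.61), 5, 3, byrow = TRUE)
  T_printed <- matrix(c(0.31, 0.05,
                        -0.78, 0.15,
                        0.02, 0.57,
                        0.54, 0.03,
                        -0.09, -0.81), 5, 2, byrow = TRUE)
  P_printed <- matrix(c(2, 0,
                        1.41, 1.41,
                        0, 2), 3, 2, byrow = TRUE)
  P_exact <- matrix(c(2, 0,
                      sqrt(2), sqrt(2),
                      0, 2), 3, 2, byrow = TRUE)
  T_exact <- procrustes_polar(center_columns(T_printed))
  list(X = X, T = T_printed, P = P_printed,
       X_exact = T_exact %*% t(P_exact), T_exact = T_exact,
       P_exact = P_exact)
}
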