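// Alternating least-squares loop for the sparse-weights estimator, in Gram
// form: everything the updates need is G = X'X (+ ridge) and ||X||_F^2,
// so the loop stays J-dimensional. The weight update reuses the LARS-EN
// kernel in larsen.cpp; the loadings update is the orthonormal polar factor
// of G W.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

arma::vec larsen_gram_cpp(const arma::mat& G, const arma::vec& b, int q,
                          double eps, int max_steps);

static arma::mat polar_factor(const arma::mat& M) {
  arma::mat U, V;
  arma::vec s;
  arma::svd_econ(U, s, V, M);
  return U * V.t();
}

// [[Rcpp::export(name = "spca_als_cpp")]]
Rcpp::List spca_als_cpp(const arma::mat& G, const arma::mat& Gq,
                        const arma::mat& P_init, const arma::mat& V_svd,
                        double ssX, int q, double lambda, double lambda2,
                        int max_iter, double tol) {
  const int J = G.n_rows, R = P_init.n_cols;
  arma::mat P = P_init, W(J, R, arma::fill::zeros);
  arma::mat bestW, bestP;
  double best_recon = arma::datum::inf, best_obj = arma::datum::inf;
  arma::vec traj(max_iter);
  double recon_prev = arma::datum::inf;
  bool converged = false;
  int reseeded = 0, it = 0;

  for (it = 1; it <= max_iter; ++it) {
    for (int r = 0; r < R; ++r) {
      arma::vec b = G * P.col(r);
      arma::vec w = larsen_gram_cpp(Gq, b, q, 1e-9, 0);
      if (arma::accu(arma::abs(w)) == 0.0 && arma::accu(arma::abs(b)) > 0.0) {
        // degenerate update: restart this component from the SVD direction
        w = larsen_gram_cpp(Gq, G * V_svd.col(r), q, 1e-9, 0);
        ++reseeded;
      }
      W.col(r) = w;
    }
    P = polar_factor(G * W);
    const arma::mat GW = G * W;
    double recon = ssX - 2.0 * arma::trace(P.t() * GW)
      + arma::trace(W.t() * GW);
    if (recon < 0.0) recon = 0.0; // guard against roundoff near exact fits
    const double obj = recon + lambda * arma::accu(arma::abs(W))
      + lambda2 * arma::accu(W % W);
    if (!std::isfinite(obj)) Rcpp::stop("objective became non-finite");
    traj[it - 1] = obj;
    if (recon < best_recon) {
      best_recon = recon;
      best_obj = obj;
      bestW = W;
      bestP = P;
    }
    if (std::isfinite(recon_prev) &&
        std::abs(recon_prev - recon) <=
          tol * std::max(recon_prev, ssX * 1e-12)) {
      converged = true;
      break;
    }
    recon_prev = recon;
  }
  if (it > max_iter) it = max_iter;
  return Rcpp::List::create(
    Rcpp::Named("W") = bestW, Rcpp::Named("P") = bestP,
    Rcpp::Named("recon") = best_recon, Rcpp::Named("obj") = best_obj,
    Rcpp::Named("trajectory") = traj.head(it),
    Rcpp::Named("n_iter") = it, Rcpp::Named("converged") = converged,
    Rcpp::Named("reseeded") = reseeded);
}
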