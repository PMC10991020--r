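// LARS elastic-net path in Gram form, truncated at a fixed active-set size.
// Mirrors larsen_gram() in R/enet.R (the reference implementation, which the
// test suite cross-checks against this kernel); compiled because the weight
// update runs once per component per alternating iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = "larsen_gram_cpp")]]
arma::vec larsen_gram_cpp(const arma::mat& G, const arma::vec& b, int q,
                          double eps = 1e-9, int max_steps = 0) {
  const int J = b.n_elem;
  if (max_steps <= 0) max_steps = 50 * J;
  arma::vec beta(J, arma::fill::zeros);
  std::vector<int> active;
  std::vector<bool> is_active(J, false);
  const double scale0 = arma::abs(b).max();
  if (scale0 == 0.0) return beta;

  for (int step = 0; step < max_steps; ++step) {
    arma::vec cvec = b - G * beta;
    double Cmax = -1.0;
    for (int j = 0; j < J; ++j)
      if (!is_active[j] && std::abs(cvec[j]) > Cmax) Cmax = std::abs(cvec[j]);
    if (Cmax <= eps * scale0) break;

    std::vector<int> entering;
    for (int j = 0; j < J; ++j)
      if (!is_active[j] && std::abs(cvec[j]) >= Cmax - eps * scale0)
        entering.push_back(j);
    if ((int)(active.size() + entering.size()) > q) break;
    for (int j : entering) { active.push_back(j); is_active[j] = true; }

    const int a = active.size();
    arma::uvec ai(a);
    arma::vec s(a);
    for (int i = 0; i < a; ++i) {
      ai[i] = active[i];
      s[i] = cvec[active[i]] >= 0 ? 1.0 : -1.0;
    }
    arma::mat GA = G.submat(ai, ai) % (s * s.t());
    arma::vec w;
    bool ok = arma::solve(w, GA, arma::ones(a), arma::solve_opts::no_approx);
    if (!ok || arma::accu(w) <= 0.0) {
      for (int j : entering) { is_active[j] = false; }
      active.resize(active.size() - entering.size());
      break;
    }
    const double AA = 1.0 / std::sqrt(arma::accu(w));
    arma::vec d = s % (AA * w);
    arma::vec avec = G.cols(ai) * d;

    double Cact = 0.0;
    for (int i = 0; i < a; ++i)
      Cact = std::max(Cact, std::abs(cvec[active[i]]));
    double gamma = Cact / AA;
    for (int j = 0; j < J; ++j) {
      if (is_active[j]) continue;
      const double c1 = (Cact - cvec[j]) / (AA - avec[j]);
      const double c2 = (Cact + cvec[j]) / (AA + avec[j]);
      if (std::isfinite(c1) && c1 > eps * Cact / AA && c1 < gamma) gamma = c1;
      if (std::isfinite(c2) && c2 > eps * Cact / AA && c2 < gamma) gamma = c2;
    }
    // lasso modification: drop an active coefficient that crosses zero
    int idrop = -1;
    double gdrop = gamma;
    for (int i = 0; i < a; ++i) {
      const double g = -beta[active[i]] / d[i];
      if (std::isfinite(g) && g > 0.0 && g < gdrop) { gdrop = g; idrop = i; }
    }
    if (idrop >= 0) gamma = gdrop;
    for (int i = 0; i < a; ++i) beta[active[i]] += gamma * d[i];
    if (idrop >= 0) {
      const int jd = active[idrop];
      beta[jd] = 0.0;
      is_active[jd] = false;
      active.erase(active.begin() + idrop);
    }
  }
  return beta;
}
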