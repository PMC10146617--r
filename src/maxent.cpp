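// Gradient-ascent fitting of the pairwise maximum-entropy (Ising) model by
// exact enumeration of all 2^M states. Feasible for M <= 12; the tight inner
// loop is in C++ because calibration and power analyses perform tens of
// thousands of fits.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// S: (2^M x M) state matrix in {-1,+1}; emp_m, emp_C: empirical moments
// <s_i>, <s_i s_j>; free_h / free_J mark parameters updated freely (moments
// strictly inside (-1,1)); the rest are clipped to +/- h_max with the sign of
// their empirical moment and excluded from the convergence check.
// [[Rcpp::export]]
List fit_maxent_core(const arma::mat& S, const arma::vec& emp_m,
                     const arma::mat& emp_C, double lr, double tol,
                     int max_iter, double h_max,
                     const arma::uvec& free_h, const arma::umat& free_J) {
  const arma::uword M = S.n_cols;
  arma::vec h(M, arma::fill::zeros);
  arma::mat J(M, M, arma::fill::zeros);

  // clipped parameters sit at the boundary from the start
  for (arma::uword i = 0; i < M; ++i)
    if (!free_h(i)) h(i) = (emp_m(i) >= 0 ? h_max : -h_max);
  for (arma::uword i = 0; i < M; ++i)
    for (arma::uword j = 0; j < M; ++j)
      if (i != j && !free_J(i, j)) J(i, j) = (emp_C(i, j) >= 0 ? h_max : -h_max);

  double mismatch = R_PosInf;
  int iter = 0;
  arma::vec p, E, m;
  arma::mat C;
  // heavy-ball momentum: the ascent direction accumulates over iterations,
  // which removes the logarithmic creep of plain fixed-step ascent when a
  // fitted parameter is large (moments close to +/-1)
  const double beta = 0.8;
  arma::vec vh(M, arma::fill::zeros);
  arma::mat vJ(M, M, arma::fill::zeros);
  for (iter = 0; iter < max_iter; ++iter) {
    E = -(S * h) - 0.5 * arma::sum((S * J) % S, 1);
    arma::vec logp = -E;
    logp -= logp.max();
    p = arma::exp(logp);
    p /= arma::accu(p);

    m = S.t() * p;
    C = S.t() * (S.each_col() % p);

    mismatch = 0.0;
    for (arma::uword i = 0; i < M; ++i) {
      if (free_h(i)) {
        double g = emp_m(i) - m(i);
        vh(i) = beta * vh(i) + lr * g;
        h(i) += vh(i);
        mismatch = std::max(mismatch, std::abs(g));
      }
      for (arma::uword j = i + 1; j < M; ++j) {
        if (free_J(i, j)) {
          double g = emp_C(i, j) - C(i, j);
          vJ(i, j) = beta * vJ(i, j) + lr * g;
          J(i, j) += vJ(i, j);
          J(j, i) = J(i, j);
          mismatch = std::max(mismatch, std::abs(g));
        }
      }
    }
    if (mismatch < tol) { ++iter; break; }
  }
  J.diag().zeros();
  return List::create(_["h"] = h, _["J"] = J, _["iterations"] = iter,
                      _["mismatch"] = mismatch,
                      _["converged"] = (mismatch < tol));
}
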