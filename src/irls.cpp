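#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Ridge-penalised IRLS for binary logistic regression.
// X carries no intercept column; the design is [1 | X] and the intercept is
// unpenalised. Weights are floored to keep the working response finite when
// fitted probabilities saturate (separation is handled by the ridge).
static arma::vec irls_ridge(const arma::mat& X, const arma::vec& y, double ridge,
                            int max_iter, double tol, int& iter_out, bool& converged) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat A(n, p + 1);
  A.col(0).ones();
  if (p > 0) A.cols(1, p) = X;
  arma::vec beta(p + 1, arma::fill::zeros);
  arma::mat pen(p + 1, p + 1, arma::fill::zeros);
  for (arma::uword j = 1; j <= p; ++j) pen(j, j) = ridge;
  converged = false;
  iter_out = 0;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec eta = A * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat Aw = A.each_col() % w;
    arma::vec rhs = A.t() * (w % z);
    arma::vec beta_new = arma::solve(A.t() * Aw + pen, rhs,
                                     arma::solve_opts::likely_sympd);
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    iter_out = it + 1;
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  return beta;
}

// [[Rcpp::export]]
List irls_ridge_cpp(const arma::mat& X, const arma::vec& y, double ridge,
                    int max_iter, double tol) {
  int iters = 0;
  bool conv = false;
  arma::vec beta = irls_ridge(X, y, ridge, max_iter, tol, iters, conv);
  return List::create(_["coefficients"] = beta,
                      _["iterations"] = iters,
                      _["converged"] = conv);
}

// Pooled out-of-fold scores for a collection of marker subsets under one
// shared fold assignment. fold is 0-based of length n; subsets holds 0-based
// column indices into X. Standardisation (center/scale) is learned on each
// training fold and applied frozen to the held-out fold, mirroring the
// single-model fitting contract.
// [[Rcpp::export]]
arma::mat cv_pool_scores_cpp(const arma::mat& X, const arma::vec& y,
                             const arma::ivec& fold, int n_folds,
                             const List& subsets, double ridge,
                             int max_iter, double tol) {
  const arma::uword n = X.n_rows;
  const int S = subsets.size();
  arma::mat scores(n, S, arma::fill::zeros);

  for (int f = 0; f < n_folds; ++f) {
    arma::uvec tr = arma::find(fold != f);
    arma::uvec te = arma::find(fold == f);
    if (te.n_elem == 0) continue;
    arma::mat Xtr = X.rows(tr);
    arma::mat Xte = X.rows(te);
    arma::rowvec ctr = arma::mean(Xtr, 0);
    arma::rowvec scl = arma::stddev(Xtr, 0, 0);
    scl.transform([](double v) { return v > 0 ? v : 1.0; });
    Xtr.each_row() -= ctr;
    Xtr.each_row() /= scl;
    Xte.each_row() -= ctr;
    Xte.each_row() /= scl;
    arma::vec ytr = y.elem(tr);

    for (int s = 0; s < S; ++s) {
      arma::uvec cols = as<arma::uvec>(subsets[s]);
      int iters = 0;
      bool conv = false;
      arma::vec beta = irls_ridge(Xtr.cols(cols), ytr, ridge, max_iter, tol,
                                  iters, conv);
      arma::vec eta = beta(0) + Xte.cols(cols) * beta.subvec(1, cols.n_elem);
      arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
      for (arma::uword i = 0; i < te.n_elem; ++i) scores(te(i), s) = pr(i);
    }
  }
  return scores;
}
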