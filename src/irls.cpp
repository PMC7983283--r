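// Iteratively reweighted least squares for Bernoulli/logit regression and
// the two-level (donor, then cell) cluster bootstrap built on top of it.
// Kept in C++ because the study harness refits the same small-P model tens
// of thousands of times on 10^4-scale cell tables.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MU_EPS = 1e-10;

// One logistic fit starting from beta (warm start allowed). lambda > 0
// adds an L2 penalty on all columns except the first (intercept).
// Convergence is declared on the relative coefficient change; the
// deviance is computed once at the solution.
static bool irls_fit(const arma::mat& X, const arma::vec& y, double lambda,
                     int maxit, double tol, arma::vec& beta,
                     double& dev_out) {
  const arma::uword p = X.n_cols;
  if (beta.n_elem != p) beta.zeros(p);
  arma::vec pen(p, arma::fill::value(lambda));
  pen(0) = 0.0;  // intercept unpenalized
  bool converged = false;
  arma::vec eta = arma::clamp(X * beta, -15.0, 15.0);
  for (int it = 0; it < maxit; ++it) {
    arma::vec mu = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), MU_EPS,
                               1.0 - MU_EPS);
    arma::vec w = mu % (1.0 - mu);
    arma::vec wz = w % eta + (y - mu);
    arma::mat Xs = X.each_col() % arma::sqrt(w);
    arma::mat A = Xs.t() * Xs;  // X' W X via syrk
    A.diag() += pen;
    arma::vec b = X.t() * wz;
    arma::vec beta_new;
    if (!arma::solve(beta_new, A, b, arma::solve_opts::likely_sympd)) {
      dev_out = std::numeric_limits<double>::quiet_NaN();
      return false;
    }
    double step = arma::abs(beta_new - beta).max();
    beta = beta_new;
    // runaway coefficients mean (quasi-)separation: stop early, the
    // caller refits with the ridge penalty
    if (lambda == 0.0 && arma::abs(beta).max() > 28.0) {
      eta = arma::clamp(X * beta, -15.0, 15.0);
      break;
    }
    eta = arma::clamp(X * beta, -15.0, 15.0);
    if (step < tol * (1.0 + arma::abs(beta).max())) {
      converged = true;
      break;
    }
  }
  arma::vec mu = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), MU_EPS,
                             1.0 - MU_EPS);
  dev_out = -2.0 * arma::accu(y % arma::log(mu) +
                              (1.0 - y) % arma::log1p(-mu));
  return converged;
}

// [[Rcpp::export]]
List irls_logistic_cpp(const arma::mat& X, const arma::vec& y,
                       double ridge_fallback, int maxit = 100,
                       double tol = 1e-12) {
  arma::vec beta;
  double dev;
  bool ok = irls_fit(X, y, 0.0, maxit, tol, beta, dev);
  bool ridged = false;
  // Non-convergence or runaway coefficients signal (quasi-)separation;
  // refit with a weak L2 penalty so every replicate returns an estimate.
  if (!ok || !beta.is_finite() || arma::abs(beta).max() > 25.0) {
    ridged = true;
    beta.reset();
    ok = irls_fit(X, y, ridge_fallback, maxit, tol, beta, dev);
  }
  return List::create(_["coef"] = beta, _["converged"] = ok,
                      _["ridged"] = ridged, _["deviance"] = dev);
}

// Observed Fisher information X' W X at beta (unpenalized).
// [[Rcpp::export]]
arma::mat fisher_info_cpp(const arma::mat& X, const arma::vec& beta) {
  arma::vec eta = arma::clamp(X * beta, -15.0, 15.0);
  arma::vec mu = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), MU_EPS,
                             1.0 - MU_EPS);
  arma::mat Xs = X.each_col() % arma::sqrt(mu % (1.0 - mu));
  return Xs.t() * Xs;
}

// Two-level nonparametric bootstrap: draw J donors with replacement, then
// within each drawn donor (with multiplicity) draw its cells with
// replacement, preserving the donor's original cell count; refit the
// logistic model on each replicate. Uses R's RNG so results are
// reproducible under set.seed(). Replicates whose resample carries a
// single condition are redrawn (at most max_redraw attempts). Replicate
// fits warm-start from the full-data estimate.
// [[Rcpp::export]]
List cluster_bootstrap_cpp(const arma::mat& X, const arma::vec& y,
                           const arma::ivec& donor, int n_donor, int B,
                           double ridge_fallback, int max_redraw = 100) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  std::vector<arma::uvec> cells(n_donor);
  {
    std::vector<std::vector<arma::uword>> tmp(n_donor);
    for (arma::uword i = 0; i < n; ++i) tmp[donor(i)].push_back(i);
    for (int j = 0; j < n_donor; ++j) {
      if (tmp[j].empty()) stop("donor with no cells");
      cells[j] = arma::uvec(tmp[j]);
    }
  }
  arma::uword max_cells = 0;
  for (int j = 0; j < n_donor; ++j)
    max_cells = std::max(max_cells, cells[j].n_elem);

  // warm-start point for every replicate
  arma::vec beta_full;
  double dev;
  bool ok = irls_fit(X, y, 0.0, 100, 1e-10, beta_full, dev);
  if (!ok || !beta_full.is_finite() ||
      arma::abs(beta_full).max() > 25.0) {
    beta_full.reset();
    irls_fit(X, y, ridge_fallback, 100, 1e-10, beta_full, dev);
  }

  arma::uvec idx(max_cells * n_donor);
  arma::mat betas(B, p);
  IntegerVector ridged(B);
  for (int b = 0; b < B; ++b) {
    bool done = false;
    for (int attempt = 0; attempt < max_redraw && !done; ++attempt) {
      arma::uword pos = 0;
      for (int k = 0; k < n_donor; ++k) {
        int j = (int)(unif_rand() * n_donor);
        if (j == n_donor) j = n_donor - 1;
        const arma::uvec& cj = cells[j];
        const int nj = (int)cj.n_elem;
        for (int c = 0; c < nj; ++c) {
          int ci = (int)(unif_rand() * nj);
          if (ci == nj) ci = nj - 1;
          idx(pos++) = cj(ci);
        }
      }
      arma::uvec use = idx.head(pos);
      arma::vec yb = y.elem(use);
      double ysum = arma::accu(yb);
      if (ysum < 0.5 || ysum > pos - 0.5) continue;  // one condition only
      arma::mat Xb = X.rows(use);
      arma::vec beta = beta_full;
      bool okb = irls_fit(Xb, yb, 0.0, 15, 1e-7, beta, dev);
      if (!okb || !beta.is_finite() || arma::abs(beta).max() > 25.0) {
        beta = beta_full;
        irls_fit(Xb, yb, ridge_fallback, 15, 1e-7, beta, dev);
        ridged[b] = 1;
      }
      betas.row(b) = beta.t();
      done = true;
    }
    if (!done) stop("bootstrap replicate %d: resample had a single "
                    "condition after %d redraws", b + 1, max_redraw);
  }
  return List::create(_["betas"] = betas, _["ridged"] = ridged);
}
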