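#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the Gaussian mixed model
//   y = X beta + Z u + e,  u ~ N(0, sp2 * C),  e ~ N(0, se2 * I)
// with a flat prior on beta and inverse-Gamma(shape, scale) priors on both
// variance components. Cinv is the precomputed inverse of the phylogenetic
// correlation matrix. (beta, u) are updated jointly from their conditional
// multivariate normal (Henderson's mixed-model equations); variances from
// their conjugate inverse-Gamma conditionals. Uses R's RNG, so results are
// reproducible via set.seed() on the R side.
// [[Rcpp::export]]
List gibbs_lmm_cpp(const arma::vec& y, const arma::mat& X,
                   const arma::mat& Z, const arma::mat& Cinv,
                   int n_iter, int burn_in, int thin,
                   double prior_shape, double prior_scale,
                   bool include_u,
                   bool fix_sp, double sp2_fixed,
                   bool fix_se, double se2_fixed) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int q = include_u ? Z.n_cols : 0;
  arma::mat W = include_u ? arma::join_rows(X, Z) : X;
  const int d = p + q;
  const arma::mat WtW = W.t() * W;
  const arma::vec Wty = W.t() * y;

  double sp2 = fix_sp ? sp2_fixed : 1.0;
  double se2 = fix_se ? se2_fixed : 1.0;
  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::mat beta_store(n_keep, p);
  arma::mat u_store(n_keep, std::max(q, 1));
  arma::vec sp_store(n_keep), se_store(n_keep);
  arma::vec theta(d, arma::fill::zeros);

  RNGScope scope;
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // joint update of (beta, u)
    arma::mat prec = WtW / se2;
    if (include_u)
      prec.submat(p, p, d - 1, d - 1) += Cinv / sp2;
    prec.diag() += 1e-10;
    arma::mat L = arma::chol(prec, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), Wty / se2));
    arma::vec zr(d);
    for (int i = 0; i < d; ++i) zr(i) = R::norm_rand();
    theta = mu + arma::solve(arma::trimatu(L.t()), zr);

    // residual variance
    arma::vec r = y - W * theta;
    if (!fix_se) {
      double g = R::rgamma(prior_shape + n / 2.0,
                           1.0 / (prior_scale + arma::dot(r, r) / 2.0));
      se2 = 1.0 / g;
    }
    // phylogenetic variance
    if (include_u && !fix_sp) {
      arma::vec u = theta.subvec(p, d - 1);
      double quad = arma::as_scalar(u.t() * Cinv * u);
      double g = R::rgamma(prior_shape + q / 2.0,
                           1.0 / (prior_scale + quad / 2.0));
      sp2 = 1.0 / g;
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_store(keep, j) = theta(j);
      if (include_u)
        for (int j = 0; j < q; ++j) u_store(keep, j) = theta(p + j);
      sp_store(keep) = include_u ? sp2 : 0.0;
      se_store(keep) = se2;
      ++keep;
    }
  }
  return List::create(_["beta"] = beta_store.rows(0, keep - 1),
                      _["u"] = u_store.rows(0, keep - 1),
                      _["sigma2_phylo"] = sp_store.subvec(0, keep - 1),
                      _["sigma2_resid"] = se_store.subvec(0, keep - 1));
}
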