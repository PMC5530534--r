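// Gibbs sampler core for the hierarchical linear models of the package:
// per-coefficient normal updates with residual tracking, plus scaled
// inverse chi-square variance updates per block. Uses R's RNG so that
// set.seed() in R makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// block_type: 0 = fixed (constant prior variance), 1 = ridge (shared
// block variance with scaled-inv-chi-square update).
// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::vec& y,
                const arma::mat& X,
                const arma::ivec& block_id,     // 0-based, per column
                const arma::ivec& block_type,   // per block
                const arma::vec& prior_scale,   // S0 per block (ridge)
                const arma::vec& prior_df,      // df0 per block (ridge)
                const double resid_scale,
                const double resid_df,
                const arma::vec& init_var,      // per block
                const double init_resid,
                const bool update_var,
                const bool update_resid,
                const int n_iter, const int burn_in, const int thin) {
  const arma::uword n = y.n_elem, P = X.n_cols;
  const int n_blocks = block_type.n_elem;

  arma::vec b(P, arma::fill::zeros);
  arma::vec e = y;                 // residual y - Xb
  arma::vec xtx(P);
  for (arma::uword j = 0; j < P; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec vb(n_blocks);
  for (int k = 0; k < n_blocks; ++k) vb(k) = init_var(k);
  double ve = init_resid;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat var_chain(n_keep, n_blocks, arma::fill::zeros);
  arma::vec resid_chain(n_keep, arma::fill::zeros);
  arma::vec coef_mean(P, arma::fill::zeros), coef_m2(P, arma::fill::zeros);
  int kept = 0;

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    // coefficients
    for (arma::uword j = 0; j < P; ++j) {
      const int k = block_id(j);
      const double pv = vb(k);   // fixed blocks keep their initial value
      const double old = b(j);
      if (xtx(j) <= 0.0) {
        b(j) = std::sqrt(pv) * norm_rand();   // no data: prior draw
        continue;
      }
      const double rhs = arma::dot(X.col(j), e) + xtx(j) * old;
      const double C = xtx(j) / ve + 1.0 / pv;
      const double mean = (rhs / ve) / C;
      const double bn = mean + norm_rand() / std::sqrt(C);
      b(j) = bn;
      e -= X.col(j) * (bn - old);
    }
    // block variances
    if (update_var) {
      for (int k = 0; k < n_blocks; ++k) {
        if (block_type(k) != 1) continue;
        double ss = 0.0; int q = 0;
        for (arma::uword j = 0; j < P; ++j) {
          if (block_id(j) == k) { ss += b(j) * b(j); ++q; }
        }
        vb(k) = (prior_scale(k) + ss) / R::rchisq(prior_df(k) + q);
      }
    }
    // residual variance
    if (update_resid) {
      ve = (resid_scale + arma::dot(e, e)) / R::rchisq(resid_df + (double)n);
    }
    if (!std::isfinite(ve) || !b.is_finite()) {
      PutRNGstate();
      stop("sampler state became non-finite at iteration %d", it + 1);
    }
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++kept;
      for (arma::uword j = 0; j < P; ++j) {
        const double d = b(j) - coef_mean(j);
        coef_mean(j) += d / kept;
        coef_m2(j) += d * (b(j) - coef_mean(j));
      }
      var_chain.row(kept - 1) = vb.t();
      resid_chain(kept - 1) = ve;
    }
  }
  PutRNGstate();

  arma::vec coef_sd(P);
  for (arma::uword j = 0; j < P; ++j) {
    coef_sd(j) = kept > 1 ? std::sqrt(coef_m2(j) / (kept - 1)) : NA_REAL;
  }
  return List::create(_["coef_mean"] = coef_mean,
                      _["coef_sd"] = coef_sd,
                      _["var_chain"] = var_chain,
                      _["resid_chain"] = resid_chain,
                      _["n_kept"] = kept);
}
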