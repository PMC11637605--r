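// R-facing interface to the OU model core.

#include "ou_model.h"

// [[Rcpp::export]]
SEXP ou_model_build(Rcpp::List data) {
  Rcpp::XPtr<OUModel> xp(new OUModel(data), true);
  return xp;
}

// [[Rcpp::export]]
double ou_model_logpost(SEXP xp_, arma::vec q) {
  Rcpp::XPtr<OUModel> xp(xp_);
  return xp->logp(q);
}

// [[Rcpp::export]]
arma::vec ou_model_gradient(SEXP xp_, arma::vec q) {
  Rcpp::XPtr<OUModel> xp(xp_);
  return xp->grad(q);
}

// [[Rcpp::export]]
int ou_model_npar(SEXP xp_) {
  Rcpp::XPtr<OUModel> xp(xp_);
  return xp->npar();
}

// mean vector, total covariance and design matrix at one draw
// [[Rcpp::export]]
Rcpp::List ou_model_matrices(SEXP xp_, arma::vec q) {
  Rcpp::XPtr<OUModel> xp(xp_);
  OUModel::Pars p = xp->parse(q);
  arma::mat W = regime_weights_cpp(p.alpha, xp->N, xp->K, xp->seg_tip,
                                   xp->seg_reg, xp->seg_ta, xp->seg_tb,
                                   xp->depths, xp->root_reg);
  arma::vec rho_tips(xp->N, arma::fill::zeros);
  if (xp->kind == 2)
    for (int i = 0; i < xp->N; ++i)
      rho_tips[i] = rho_factor(p.alpha * xp->depths[i]);
  arma::vec mu = xp->mean_vec(p, W, rho_tips);
  arma::mat V = xp->cov_mat(p);
  return Rcpp::List::create(Rcpp::Named("mu") = mu, Rcpp::Named("V") = V,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("rho_tips") = rho_tips);
}

// constrained (natural-scale) parameters at one unconstrained draw
// [[Rcpp::export]]
Rcpp::List ou_model_constrain(SEXP xp_, arma::vec q) {
  Rcpp::XPtr<OUModel> xp(xp_);
  OUModel::Pars p = xp->parse(q);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("t_half") = p.thalf,
    Rcpp::Named("v") = p.v,
    Rcpp::Named("alpha") = p.alpha,
    Rcpp::Named("sigma2_y") = 2.0 * p.alpha * p.v,
    Rcpp::Named("theta") = p.theta);
  if (xp->kind > 0) out["beta"] = p.beta;
  if (xp->ml >= 1) { out["theta_bar"] = p.tbar; out["sigma_theta"] = p.st; }
  if (xp->ml == 2) {
    out["beta_bar"] = p.bbar; out["sigma_beta"] = p.sb; out["rho_cor"] = p.rho;
  }
  if (xp->kind == 2) { out["sigma2_x"] = p.s2x; out["mu_x"] = p.mux; }
  if (xp->latent_x && xp->P > 0) out["x_true"] = p.xlat;
  return out;
}

// ---- standalone math helpers (single implementation shared with the
// sampler; exposed to R through thin wrappers) ----------------------------

// [[Rcpp::export]]
arma::mat cpp_regime_weights(double alpha, int N, int K,
                             arma::ivec seg_tip, arma::ivec seg_reg,
                             arma::vec seg_ta, arma::vec seg_tb,
                             arma::vec depths, int root_reg) {
  return regime_weights_cpp(alpha, N, K, seg_tip, seg_reg, seg_ta, seg_tb,
                            depths, root_reg);
}

// [[Rcpp::export]]
arma::mat cpp_ou_covariance(double alpha, double v, arma::mat s, arma::mat d) {
  return ou_covariance_cpp(alpha, v, s, d);
}

// [[Rcpp::export]]
arma::mat cpp_adaptive_kernel(double alpha, arma::mat s, double T) {
  return adaptive_kernel_cpp(alpha, s, T);
}

// [[Rcpp::export]]
double cpp_rho_factor(double x) { return rho_factor(x); }
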