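#ifndef PHYLOU_OU_MODEL_H
#define PHYLOU_OU_MODEL_H

#include <RcppArmadillo.h>

// Generic differentiable target for the NUTS sampler.
class Target {
public:
  virtual ~Target() {}
  virtual double logp(const arma::vec& q) = 0;
  virtual arma::vec grad(const arma::vec& q) = 0;
  virtual int npar() const = 0;
};

// ---- deterministic OU math ---------------------------------------------

// phylogenetic correction factor rho(x) = 1 - (1 - e^-x)/x, rho(0) = 0
inline double rho_factor(double x) {
  if (x <= 0.0) return 0.0;
  if (x < 1e-5) return x / 2.0 - x * x / 6.0;
  return 1.0 + std::expm1(-x) / x;
}

// alpha^2 * J(t) where J is the double integral of the optimum-tracking
// history covariance (see package vignette for the derivation)
inline double a2J(double t, double a) {
  if (t <= 0.0) return 0.0;
  double e1 = std::exp(-a * t), e2 = std::exp(-2.0 * a * t);
  return t - 1.5 * (1.0 - e2) / a + 2.0 * (e1 - e2) / a;
}

// Hansen regime-weight design matrix: exponentially discounted time in each
// regime along every root-to-tip lineage; residual root mass e^{-alpha T}
// assigned to the root's regime.  Rows sum to 1 by construction.
inline arma::mat regime_weights_cpp(double alpha, int N, int K,
                                    const arma::ivec& seg_tip,
                                    const arma::ivec& seg_reg,
                                    const arma::vec& seg_ta,
                                    const arma::vec& seg_tb,
                                    const arma::vec& depths, int root_reg) {
  arma::mat W(N, K, arma::fill::zeros);
  const int S = seg_tip.n_elem;
  for (int s = 0; s < S; ++s) {
    int i = seg_tip[s];
    double Ti = depths[i];
    W(i, seg_reg[s]) +=
      std::exp(-alpha * (Ti - seg_tb[s])) - std::exp(-alpha * (Ti - seg_ta[s]));
  }
  for (int i = 0; i < N; ++i) W(i, root_reg) += std::exp(-alpha * depths[i]);
  return W;
}

// Standard Hansen OU residual covariance
inline arma::mat ou_covariance_cpp(double alpha, double v,
                                   const arma::mat& s, const arma::mat& d) {
  return v * (arma::exp(-alpha * d) % (1.0 - arma::exp(-2.0 * alpha * s)));
}

// Predictor-history covariance kernel for the adaptive model (ultrametric
// tree, common depth T): kappa_ij such that the residual covariance from the
// evolutionary regression is  b_i b_j sigma2_x kappa_ij.
inline arma::mat adaptive_kernel_cpp(double alpha, const arma::mat& s, double T) {
  const int N = s.n_rows;
  arma::mat K(N, N);
  double rhoT = rho_factor(alpha * T);
  double aJT = a2J(T, alpha);
  double eT = std::exp(-alpha * T);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sij = s(i, j);
      double G = sij - (std::exp(-alpha * (T - sij)) - eT) / alpha;
      double k = (aJT - a2J(T - sij, alpha)) - 2.0 * rhoT * G + rhoT * rhoT * sij;
      K(i, j) = k;
      K(j, i) = k;
    }
  }
  return K;
}

// ---- scalar log densities (with normalizing constants) ------------------

inline double dnorm_log(double x, double m, double sd) {
  double z = (x - m) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672742; // log(sqrt(2pi))
}

// ---- the OU model target ------------------------------------------------
//
// Unconstrained parameter layout (offsets computed in the constructor):
//   [0] log t_half, [1] log v,
//   (adaptive, est_x) log sigma2_x, mu_x,
//   theta block  : theta[K] | (theta[K] or z_theta[K]), theta_bar, log sigma_theta
//   beta block   : beta[P] | beta[K] | (beta[K] or z_beta[K]), beta_bar,
//                  log sigma_beta, atanh rho
//   latent X     : x_true[N*P]

class OUModel : public Target {
public:
  // structure
  int N, K, P, kind, ml;        // kind: 0 none, 1 direct, 2 adaptive
  bool noncentered, by_regime, est_x, latent_x, me_y;
  // data
  arma::vec y, se2_y, depths;
  arma::mat X, se_x, s, d;
  arma::ivec seg_tip, seg_reg, tip_reg;
  arma::vec seg_ta, seg_tb;
  int root_reg;
  double T;                      // common tip depth (adaptive)
  arma::mat cholS_L;             // lower chol of s (+ tiny jitter), X BM term
  double logdetS;                // log|s|
  double sigma2x_fix, mux_fix;
  double jitter_rel;
  double lat_sd_mult;
  // priors
  double pr_lt_m, pr_lt_s;
  int vtype;                     // 0 exp, 1 half-Cauchy, 2 uniform
  double pr_v1, pr_v2;
  arma::mat pr_theta, pr_beta;   // (mean, sd) rows
  double pr_tbar_m, pr_tbar_s, pr_st_rate;
  double pr_bbar_m, pr_bbar_s, pr_sb_rate, lkj_eta;
  double pr_ls2x_m, pr_ls2x_s, pr_mux_m, pr_mux_s;
  // layout
  int i_lt, i_lv, i_ls2x, i_mux, i_theta, i_tbar, i_lst,
      i_beta, i_bbar, i_lsb, i_yrho, i_xlat, n_par, n_beta;
  std::vector<int> cov_idx;      // params entering W or V
  std::vector<bool> is_cov;

  struct Pars {
    double thalf, v, alpha, s2x, mux;
    arma::vec theta, beta;       // constrained values
    double tbar, st, bbar, sb, rho;
    arma::mat xlat;              // N x P (latent true predictors)
    arma::mat ulat;              // standardized latent deviates (parameters)
  };

  // two-level cache: stage A holds the alpha-dependent matrices (reused
  // whenever alpha is unchanged, e.g. finite differences of non-half-life
  // parameters); stage C holds the Cholesky factor (reused for parameters
  // entering only the mean)
  struct Cache {
    bool avalid = false, cvalid = false;
    double alpha_c = -1.0;
    arma::mat Eou, Kker, W;      // OU kernel at v=1; adaptive kernel; design
    arma::vec rho_tips;
    arma::mat Lv;                // lower chol of V_total
    double logdetV = 0.0;
    arma::vec Vinv_r;            // V^{-1}(y - mu) at the anchor point
  };
  Cache cache;

  OUModel(const Rcpp::List& dat) {
    using Rcpp::as;
    N = as<int>(dat["N"]); K = as<int>(dat["K"]); P = as<int>(dat["P"]);
    kind = as<int>(dat["kind"]); ml = as<int>(dat["ml"]);
    noncentered = as<bool>(dat["noncentered"]);
    by_regime = as<bool>(dat["by_regime"]);
    est_x = as<bool>(dat["est_x"]);
    latent_x = as<bool>(dat["latent_x"]);
    me_y = as<bool>(dat["me_y"]);
    y = as<arma::vec>(dat["y"]); se2_y = as<arma::vec>(dat["se2_y"]);
    depths = as<arma::vec>(dat["depths"]);
    if (P > 0) { X = as<arma::mat>(dat["X"]); se_x = as<arma::mat>(dat["se_x"]); }
    s = as<arma::mat>(dat["s"]); d = as<arma::mat>(dat["d"]);
    seg_tip = as<arma::ivec>(dat["seg_tip"]); seg_reg = as<arma::ivec>(dat["seg_reg"]);
    seg_ta = as<arma::vec>(dat["seg_ta"]); seg_tb = as<arma::vec>(dat["seg_tb"]);
    tip_reg = as<arma::ivec>(dat["tip_reg"]);
    root_reg = as<int>(dat["root_reg"]);
    T = as<double>(dat["T"]);
    sigma2x_fix = as<double>(dat["sigma2x_fix"]);
    mux_fix = as<double>(dat["mux_fix"]);
    jitter_rel = as<double>(dat["jitter_rel"]);
    lat_sd_mult = as<double>(dat["lat_sd_mult"]);

    Rcpp::List pr = dat["priors"];
    arma::vec plt = as<arma::vec>(pr["lt"]);
    pr_lt_m = plt[0]; pr_lt_s = plt[1];
    vtype = as<int>(pr["vtype"]);
    arma::vec pv = as<arma::vec>(pr["v"]);
    pr_v1 = pv[0]; pr_v2 = pv.n_elem > 1 ? pv[1] : 0.0;
    pr_theta = as<arma::mat>(pr["theta"]);
    pr_beta = as<arma::mat>(pr["beta"]);
    arma::vec ptb = as<arma::vec>(pr["tbar"]);
    pr_tbar_m = ptb[0]; pr_tbar_s = ptb[1];
    pr_st_rate = as<double>(pr["st_rate"]);
    arma::vec pbb = as<arma::vec>(pr["bbar"]);
    pr_bbar_m = pbb[0]; pr_bbar_s = pbb[1];
    pr_sb_rate = as<double>(pr["sb_rate"]);
    lkj_eta = as<double>(pr["lkj_eta"]);
    arma::vec ps2x = as<arma::vec>(pr["ls2x"]);
    pr_ls2x_m = ps2x[0]; pr_ls2x_s = ps2x[1];
    arma::vec pmx = as<arma::vec>(pr["mux"]);
    pr_mux_m = pmx[0]; pr_mux_s = pmx[1];

    // X Brownian-motion factor (adaptive): chol of s with tiny jitter
    if (kind == 2) {
      arma::mat Sj = s;
      Sj.diag() += 1e-10 * Sj.diag().max();
      if (!arma::chol(cholS_L, Sj, "lower"))
        Rcpp::stop("shared-time matrix is not positive definite");
      logdetS = 2.0 * arma::accu(arma::log(cholS_L.diag()));
    }

    // ---- layout ----
    int k = 0;
    i_lt = k++; i_lv = k++;
    i_ls2x = i_mux = -1;
    if (kind == 2 && est_x) { i_ls2x = k++; i_mux = k++; }
    i_theta = k; k += K;
    i_tbar = i_lst = -1;
    if (ml >= 1) { i_tbar = k++; i_lst = k++; }
    i_beta = i_bbar = i_lsb = i_yrho = -1;
    n_beta = 0;
    if (kind > 0) {
      n_beta = by_regime ? K : P;
      i_beta = k; k += n_beta;
      if (ml == 2) { i_bbar = k++; i_lsb = k++; i_yrho = k++; }
    }
    i_xlat = -1;
    if (latent_x && P > 0) { i_xlat = k; k += N * P; }
    n_par = k;

    is_cov.assign(n_par, false);
    is_cov[i_lt] = true; is_cov[i_lv] = true;
    if (kind == 2) {
      if (est_x) is_cov[i_ls2x] = true;
      // any parameter that determines the beta values perturbs V
      for (int j = 0; j < n_beta; ++j) is_cov[i_beta + j] = true;
      if (ml == 2 && noncentered) {
        for (int j = 0; j < K; ++j) is_cov[i_theta + j] = true; // z_theta feeds beta
        is_cov[i_bbar] = true; is_cov[i_lsb] = true; is_cov[i_yrho] = true;
      }
    }
    for (int j = 0; j < n_par; ++j) if (is_cov[j]) cov_idx.push_back(j);
  }

  int npar() const { return n_par; }

  Pars parse(const arma::vec& q) const {
    Pars p;
    p.thalf = std::exp(q[i_lt]);
    p.alpha = M_LN2 / p.thalf;
    p.v = std::exp(q[i_lv]);
    p.s2x = (kind == 2) ? (est_x ? std::exp(q[i_ls2x]) : sigma2x_fix) : 0.0;
    p.mux = (kind == 2) ? (est_x ? q[i_mux] : mux_fix) : 0.0;
    p.tbar = (ml >= 1) ? q[i_tbar] : 0.0;
    p.st = (ml >= 1) ? std::exp(q[i_lst]) : 0.0;
    p.bbar = (ml == 2) ? q[i_bbar] : 0.0;
    p.sb = (ml == 2) ? std::exp(q[i_lsb]) : 0.0;
    p.rho = (ml == 2) ? std::tanh(q[i_yrho]) : 0.0;
    arma::vec tpar = q.subvec(i_theta, i_theta + K - 1);
    if (ml >= 1 && noncentered) p.theta = p.tbar + p.st * tpar;
    else p.theta = tpar;
    if (kind > 0) {
      arma::vec bpar = q.subvec(i_beta, i_beta + n_beta - 1);
      if (ml == 2 && noncentered) {
        double rr = std::sqrt(std::max(0.0, 1.0 - p.rho * p.rho));
        p.beta = p.bbar + p.sb * (p.rho * tpar + rr * bpar);
      } else p.beta = bpar;
    }
    if (latent_x && P > 0) {
      // latent true predictors parameterized as x = x_obs + se * u
      p.ulat = arma::reshape(q.subvec(i_xlat, i_xlat + N * P - 1), N, P);
      p.xlat = X + se_x % p.ulat;
    }
    return p;
  }

  // log prior (+ Jacobians), all constants included
  double log_prior(const arma::vec& q, const Pars& p) const {
    double lp = 0.0;
    lp += dnorm_log(q[i_lt], pr_lt_m, pr_lt_s);
    // v prior with log-scale Jacobian
    if (vtype == 0) lp += std::log(pr_v1) - pr_v1 * p.v + q[i_lv];
    else if (vtype == 1)
      lp += std::log(2.0 / M_PI) - std::log(pr_v1)
            - std::log1p((p.v / pr_v1) * (p.v / pr_v1)) + q[i_lv];
    else {
      if (p.v < pr_v1 || p.v > pr_v2) return -arma::datum::inf;
      lp += -std::log(pr_v2 - pr_v1) + q[i_lv];
    }
    if (kind == 2 && est_x) {
      lp += dnorm_log(q[i_ls2x], pr_ls2x_m, pr_ls2x_s);
      lp += dnorm_log(q[i_mux], pr_mux_m, pr_mux_s);
    }
    // theta block
    if (ml == 0) {
      for (int k = 0; k < K; ++k)
        lp += dnorm_log(p.theta[k], pr_theta(k % pr_theta.n_rows, 0),
                        pr_theta(k % pr_theta.n_rows, 1));
    } else {
      lp += dnorm_log(p.tbar, pr_tbar_m, pr_tbar_s);
      lp += std::log(pr_st_rate) - pr_st_rate * p.st + q[i_lst];
      if (noncentered) {
        for (int k = 0; k < K; ++k) lp += dnorm_log(q[i_theta + k], 0.0, 1.0);
      } else if (ml == 1 || kind == 0 || !by_regime) {
        for (int k = 0; k < K; ++k) lp += dnorm_log(p.theta[k], p.tbar, p.st);
      }
      // centered varying-effects joint prior handled with the beta block
    }
    // beta block
    if (kind > 0) {
      if (ml < 2) {
        for (int j = 0; j < n_beta; ++j)
          lp += dnorm_log(p.beta[j], pr_beta(j % pr_beta.n_rows, 0),
                          pr_beta(j % pr_beta.n_rows, 1));
      } else {
        lp += dnorm_log(p.bbar, pr_bbar_m, pr_bbar_s);
        lp += std::log(pr_sb_rate) - pr_sb_rate * p.sb + q[i_lsb];
        double r = p.rho, om = 1.0 - r * r;
        // LKJ(eta) on the 2x2 correlation + tanh Jacobian
        lp += -(std::lgamma(lkj_eta) * 2.0 - std::lgamma(2.0 * lkj_eta))
              - (2.0 * lkj_eta - 1.0) * std::log(2.0)
              + (lkj_eta - 1.0) * std::log(om) + std::log(om);
        if (noncentered) {
          for (int j = 0; j < n_beta; ++j) lp += dnorm_log(q[i_beta + j], 0.0, 1.0);
        } else {
          // centered joint MVN2 prior on (theta_k, beta_k)
          for (int k = 0; k < K; ++k) {
            double a = (p.theta[k] - p.tbar) / p.st;
            double b = (p.beta[k] - p.bbar) / p.sb;
            lp += -std::log(2.0 * M_PI) - std::log(p.st * p.sb)
                  - 0.5 * std::log(om)
                  - 0.5 * (a * a - 2.0 * r * a * b + b * b) / om;
          }
        }
      }
    }
    return lp;
  }

  // per-tip slope vector (adaptive covariance and mean)
  arma::vec beta_tip(const Pars& p) const {
    arma::vec b(N);
    for (int i = 0; i < N; ++i)
      b[i] = by_regime ? p.beta[tip_reg[i]] : p.beta[0];
    return b;
  }

  arma::vec mean_vec(const Pars& p, const arma::mat& W,
                     const arma::vec& rho_tips) const {
    arma::vec mu = W * p.theta;
    if (kind == 1) {
      const arma::mat& Xu = latent_x ? p.xlat : X;
      if (by_regime) {
        for (int i = 0; i < N; ++i) mu[i] += p.beta[tip_reg[i]] * Xu(i, 0);
      } else mu += Xu * p.beta;
    } else if (kind == 2) {
      const arma::mat& Xu = latent_x ? p.xlat : X;
      arma::vec bt = beta_tip(p);
      mu += bt % rho_tips % Xu.col(0);
    }
    return mu;
  }

  arma::mat cov_mat(const Pars& p) const {
    arma::mat V = ou_covariance_cpp(p.alpha, p.v, s, d);
    if (kind == 2) {
      arma::vec bt = beta_tip(p);
      V += p.s2x * ((bt * bt.t()) % adaptive_kernel_cpp(p.alpha, s, T));
    }
    if (me_y) V.diag() += se2_y;
    V.diag() += jitter_rel * p.v;
    return V;
  }

  // X-side terms: BM structural model (adaptive), latent priors, obs model.
  // With the standardized latent parameterization the observation model and
  // the change-of-variable Jacobian combine into a standard normal on u.
  double log_x_terms(const Pars& p) const {
    double lp = 0.0;
    if (kind == 2) {
      const arma::vec xs = (latent_x ? p.xlat.col(0) : X.col(0));
      arma::vec z = arma::solve(arma::trimatl(cholS_L), xs - p.mux);
      lp += -0.5 * arma::dot(z, z) / p.s2x
            - 0.5 * (logdetS + N * std::log(p.s2x))
            - 0.5 * N * std::log(2.0 * M_PI);
    }
    if (latent_x && P > 0) {
      for (int j = 0; j < P; ++j)
        for (int i = 0; i < N; ++i) {
          lp += dnorm_log(p.ulat(i, j), 0.0, 1.0);  // obs model + Jacobian
          if (kind == 1)                            // weak prior on x_true
            lp += dnorm_log(p.xlat(i, j), X(i, j), lat_sd_mult * se_x(i, j));
        }
    }
    return lp;
  }

  // mode: 0 plain (reuse stage A when alpha matches), 1 fill the Cholesky
  // cache, 2 reuse the Cholesky cache (mean-only parameter perturbations)
  double logp_impl(const arma::vec& q, int mode) {
    Pars p = parse(q);
    double lp = log_prior(q, p);
    if (!std::isfinite(lp)) return -arma::datum::inf;

    if (!(cache.avalid && p.alpha == cache.alpha_c)) build_stage_a(p.alpha);
    arma::vec mu = mean_vec(p, cache.W, cache.rho_tips);
    arma::vec r = y - mu;

    double logdetV;
    arma::vec z;
    if (mode == 2 && cache.cvalid) {
      z = arma::solve(arma::trimatl(cache.Lv), r);
      logdetV = cache.logdetV;
    } else {
      // fused single-pass assembly of V_total (no temporaries)
      arma::mat V(N, N);
      if (kind == 2) {
        arma::vec bt = beta_tip(p);
        for (int jc = 0; jc < N; ++jc) {
          for (int ir = 0; ir <= jc; ++ir) {
            double val = p.v * cache.Eou(ir, jc) +
                         p.s2x * bt[ir] * bt[jc] * cache.Kker(ir, jc);
            V(ir, jc) = val;
            V(jc, ir) = val;
          }
        }
      } else {
        for (int jc = 0; jc < N; ++jc)
          for (int ir = 0; ir <= jc; ++ir) {
            double val = p.v * cache.Eou(ir, jc);
            V(ir, jc) = val;
            V(jc, ir) = val;
          }
      }
      if (me_y) V.diag() += se2_y;
      V.diag() += jitter_rel * p.v;
      arma::mat L;
      if (!arma::chol(L, V, "lower")) return -arma::datum::inf;
      z = arma::solve(arma::trimatl(L), r);
      logdetV = 2.0 * arma::accu(arma::log(L.diag()));
      if (mode == 1) {
        cache.Lv = L; cache.logdetV = logdetV; cache.cvalid = true;
        cache.Vinv_r = arma::solve(arma::trimatu(L.t()), z);
      }
    }
    lp += -0.5 * arma::dot(z, z) - 0.5 * logdetV
          - 0.5 * N * std::log(2.0 * M_PI);
    lp += log_x_terms(p);
    return lp;
  }

  // fused single-pass build of the alpha-dependent matrices (OU kernel at
  // v = 1, adaptive predictor-history kernel, design matrix, rho factors)
  void build_stage_a(double alpha) {
    cache.W = regime_weights_cpp(alpha, N, K, seg_tip, seg_reg, seg_ta,
                                 seg_tb, depths, root_reg);
    cache.Eou.set_size(N, N);
    cache.rho_tips.zeros(N);
    if (kind == 2) {
      cache.Kker.set_size(N, N);
      double rhoT = rho_factor(alpha * T);
      double aJT = a2J(T, alpha);
      double eT = std::exp(-alpha * T);
      for (int jc = 0; jc < N; ++jc)
        for (int ir = 0; ir <= jc; ++ir) {
          double sij = s(ir, jc);
          double x1 = std::exp(-alpha * (T - sij));       // e^{-a(T-s)}
          double e2s = std::exp(-2.0 * alpha * sij);      // e^{-2as}
          double eou = std::exp(-alpha * d(ir, jc)) * (1.0 - e2s);
          cache.Eou(ir, jc) = eou; cache.Eou(jc, ir) = eou;
          // a2J(T - s): uses x1 and x1^2
          double ts = T - sij;
          double aj = ts - 1.5 * (1.0 - x1 * x1) / alpha
                      + 2.0 * (x1 - x1 * x1) / alpha;
          double G = sij - (x1 - eT) / alpha;
          double kk = (aJT - aj) - 2.0 * rhoT * G + rhoT * rhoT * sij;
          cache.Kker(ir, jc) = kk; cache.Kker(jc, ir) = kk;
        }
      for (int i = 0; i < N; ++i)
        cache.rho_tips[i] = rho_factor(alpha * depths[i]);
    } else {
      for (int jc = 0; jc < N; ++jc)
        for (int ir = 0; ir <= jc; ++ir) {
          double eou = std::exp(-alpha * d(ir, jc)) *
                       (1.0 - std::exp(-2.0 * alpha * s(ir, jc)));
          cache.Eou(ir, jc) = eou; cache.Eou(jc, ir) = eou;
        }
    }
    cache.alpha_c = alpha;
    cache.avalid = true;
    cache.cvalid = false;
  }

  double logp(const arma::vec& q) { return logp_impl(q, 0); }

  // gradient: analytic for everything that perturbs the covariance except
  // the half-life (standard identities dlp = -0.5 tr(V^-1 dV) + 0.5 u'dV u
  // + dmu'u with u = V^-1 r), cached-factor central differences for
  // remaining mean-only parameters, full central differences for log t_half
  arma::vec grad(const arma::vec& q) {
    arma::vec g(n_par, arma::fill::zeros);
    cache.avalid = false; cache.cvalid = false;
    double lp0 = logp_impl(q, 1);  // anchor: fills both cache stages at q
    if (!std::isfinite(lp0) || !cache.cvalid) return g;
    analytic_cov_grad(q, g);
    // latent-predictor deviates enter the posterior linearly in the mean and
    // quadratically in their own Gaussian terms: gradient in closed form
    if (latent_x && P > 0) {
      Pars p = parse(q);
      arma::vec bt = (kind > 0) ? beta_tip(p) : arma::vec(N, arma::fill::zeros);
      arma::vec Sinv_xm;
      if (kind == 2) {
        arma::vec w = arma::solve(arma::trimatl(cholS_L),
                                  arma::vec(p.xlat.col(0)) - p.mux);
        Sinv_xm = arma::solve(arma::trimatu(cholS_L.t()), w);
      }
      for (int j = 0; j < P; ++j)
        for (int i = 0; i < N; ++i) {
          double dmu = 0.0;
          if (kind == 2) dmu = bt[i] * cache.rho_tips[i] * se_x(i, j);
          else if (kind == 1)
            dmu = (by_regime ? p.beta[tip_reg[i]] : p.beta[j]) * se_x(i, j);
          double gj = cache.Vinv_r[i] * dmu - p.ulat(i, j);
          if (kind == 2) gj -= se_x(i, j) * Sinv_xm[i] / p.s2x;
          else gj -= p.ulat(i, j) / (lat_sd_mult * lat_sd_mult);
          g[i_xlat + j * N + i] = gj;
        }
    }
    arma::vec qq = q;
    auto diff = [&](int j, int mode) {
      double h = 6e-6 * std::max(1.0, std::fabs(q[j]));
      qq[j] = q[j] + h;
      double f1 = logp_impl(qq, mode);
      qq[j] = q[j] - h;
      double f2 = logp_impl(qq, mode);
      qq[j] = q[j];
      double gj = (f1 - f2) / (2.0 * h);
      return std::isfinite(gj) ? gj : 0.0;
    };
    int lat_lo = (latent_x && P > 0) ? i_xlat : n_par;
    for (int j = 0; j < n_par; ++j)
      if (!is_cov[j] && !(j >= lat_lo)) g[j] = diff(j, 2);
    g[i_lt] = diff(i_lt, 0);  // last: perturbs alpha, clobbers stage A
    cache.avalid = false; cache.cvalid = false;
    return g;
  }

  // closed-form gradients for the covariance-perturbing parameters other
  // than the half-life: log v, log sigma2_x, and (adaptive model) every
  // parameter feeding the per-tip slopes
  void analytic_cov_grad(const arma::vec& q, arma::vec& g) {
    Pars p = parse(q);
    const arma::vec& u = cache.Vinv_r;
    arma::mat Li = arma::inv(arma::trimatl(cache.Lv));
    arma::mat Vinv = Li.t() * Li;

    // d lp / d log v
    double trE = arma::accu(Vinv % cache.Eou) + jitter_rel * arma::trace(Vinv);
    double quadE = arma::dot(u, cache.Eou * u) + jitter_rel * arma::dot(u, u);
    double dpr_lv;
    if (vtype == 0) dpr_lv = 1.0 - pr_v1 * p.v;
    else if (vtype == 1) {
      double t2 = (p.v / pr_v1) * (p.v / pr_v1);
      dpr_lv = 1.0 - 2.0 * t2 / (1.0 + t2);
    } else dpr_lv = 1.0;
    g[i_lv] = p.v * (-0.5 * trE + 0.5 * quadE) + dpr_lv;

    if (kind != 2) return;

    arma::vec b = beta_tip(p);
    arma::mat VK = Vinv % cache.Kker;
    arma::vec VKb = VK * b;
    arma::vec ubv = u % b;
    arma::vec Kub = cache.Kker * ubv;
    const arma::vec xs = (latent_x ? p.xlat.col(0) : X.col(0));

    if (est_x) {
      arma::vec w = arma::solve(arma::trimatl(cholS_L), xs - p.mux);
      double quadx = arma::dot(w, w);
      double trX = arma::dot(b, VKb);
      double quadX = arma::dot(ubv, Kub);
      g[i_ls2x] = p.s2x * (-0.5 * trX + 0.5 * quadX)
                  + 0.5 * quadx / p.s2x - 0.5 * N
                  - (q[i_ls2x] - pr_ls2x_m) / (pr_ls2x_s * pr_ls2x_s);
    }

    // dlp/d b_i (per-tip slope), covariance and mean parts
    arma::vec gb = p.s2x * (-VKb + u % Kub) + cache.rho_tips % xs % u;
    // per-regime (or total) sums
    arma::vec greg(std::max(n_beta, 1), arma::fill::zeros);
    if (by_regime) {
      for (int i = 0; i < N; ++i) greg[tip_reg[i]] += gb[i];
    } else greg[0] = arma::accu(gb);

    if (ml < 2) {
      for (int j = 0; j < n_beta; ++j) {
        double m0 = pr_beta(j % pr_beta.n_rows, 0),
               s0 = pr_beta(j % pr_beta.n_rows, 1);
        g[i_beta + j] = greg[j] - (p.beta[j] - m0) / (s0 * s0);
      }
      return;
    }

    double r = p.rho, om = 1.0 - r * r;
    double rr = std::sqrt(std::max(1e-12, om));
    if (!noncentered) {
      // centered: beta_k are parameters with the MVN2 prior
      for (int k = 0; k < K; ++k) {
        double a = (p.theta[k] - p.tbar) / p.st;
        double bb = (p.beta[k] - p.bbar) / p.sb;
        g[i_beta + k] = greg[k] - (bb - r * a) / (om * p.sb);
      }
      return;
    }
    // non-centered: beta_k = bbar + sb (r z_t + sqrt(1-r^2) z_b)
    double sum_g = 0.0, sum_lsb = 0.0, sum_rho = 0.0;
    for (int k = 0; k < K; ++k) {
      double ztk = q[i_theta + k], zbk = q[i_beta + k];
      // z_theta: mean part (theta_k = tbar + st z_t) + slope part + prior
      g[i_theta + k] = p.st * arma::dot(cache.W.col(k), u)
                       + greg[k] * p.sb * r - ztk;
      g[i_beta + k] = greg[k] * p.sb * rr - zbk;
      sum_g += greg[k];
      sum_lsb += greg[k] * (p.beta[k] - p.bbar);
      sum_rho += greg[k] * p.sb * (ztk - r * zbk / rr);
    }
    g[i_bbar] = sum_g - (p.bbar - pr_bbar_m) / (pr_bbar_s * pr_bbar_s);
    g[i_lsb] = sum_lsb + 1.0 - pr_sb_rate * p.sb;
    g[i_yrho] = sum_rho * om - 2.0 * r * lkj_eta;
  }
};

#endif
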