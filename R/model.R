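# Assembly of model mean vectors and total covariance matrices for all
# implemented model kinds, and construction of the C++ model object used by
# the sampler.
#
# Adaptive model (optimum tracks a Brownian-motion predictor): conditional on
# the observed predictor, the tip-level (evolutionary) regression slope is
# beta_optimal * rho(alpha T) and the residual covariance is
#   V_ij = v e^{-alpha d_ij}(1 - e^{-2 alpha s_ij})
#        + b_i b_j sigma2_x kappa_ij
# where kappa encodes the exponentially discounted covariance of the
# predictor history (see the methods vignette for the derivation and its
# Monte-Carlo validation against the generative SDE).

#' Model mean vector
#'
#' Multi-optima: `mu = W theta`.  Direct effect adds `X beta` (slope per
#' regime when `slopes = "by_regime"`).  Adaptive adds the rho-discounted
#' regression of the optimum on the predictor, `beta * rho(alpha T_i) * x_i`,
#' so the implied tip-level slope is the optimal slope times `rho`.
#'
#' @param tree A `phylou_tree`.
#' @param painting A `phylou_painting`.
#' @param spec A `phylou_spec`.
#' @param params Named list with `t_half` (or `alpha`), `theta` (length K),
#'   and for predictor models `beta` (length 1/P, or K for by-regime slopes).
#' @param X Predictor matrix/vector (already centered if the intercepts are
#'   to be read at the predictor mean).
#' @return Named mean vector (tip order).
#' @export
model_mean <- function(tree, painting, spec, params, X = NULL) {
  tree <- as_phylou_tree_keep_scale(tree)
  kind <- spec_kind_code(spec)
  alpha <- params$alpha
  if (is.null(alpha)) alpha <- half_life_to_alpha(params$t_half)
  K <- length(painting$regime_names)
  theta <- rep(params$theta, length.out = K)
  W <- regime_weights(alpha, tree, painting)
  mu <- as.numeric(W %*% theta)
  if (kind > 0) {
    if (is.null(X)) stop("predictor values X required for ", spec$kind)
    X <- as.matrix(X)
    beta <- params$beta
    if (is.null(beta)) stop("params$beta required for ", spec$kind)
    treg <- tip_regimes(tree, painting)
    if (kind == 1) {
      if (spec$slopes == "by_regime") {
        beta <- rep(beta, length.out = K)
        mu <- mu + beta[treg] * X[, 1]
      } else {
        mu <- mu + as.numeric(X %*% rep(beta, length.out = ncol(X)))
      }
    } else {
      if (!is_ultrametric(tree))
        stop("the adaptive model requires an ultrametric tree")
      rho <- rho_correction(alpha, unname(tip_depths(tree)))
      bt <- if (spec$slopes == "by_regime") rep(beta, length.out = K)[treg]
            else rep(beta[1], n_tips(tree))
      mu <- mu + bt * rho * X[, 1]
    }
  }
  setNames(mu, tip_labels(tree))
}

#' Model total covariance matrix
#'
#' Multi-optima and direct-effect models: the OU residual covariance.  The
#' adaptive model adds the predictor-history variance terms
#' `b_i b_j sigma2_x kappa_ij`.  Response measurement error (when handled by
#' marginalized latent values) adds `se_y^2` to the diagonal.  A relative
#' jitter of `1e-10 v` is added to the diagonal before factorization.
#'
#' @inheritParams model_mean
#' @param params Also uses `v` (stationary variance) and, for the adaptive
#'   model, `sigma2_x` (predictor BM variance).
#' @param se_y Optional response standard errors (diagonal inflation).
#' @return N x N covariance matrix (tip order).
#' @export
model_covariance <- function(tree, painting, spec, params, se_y = NULL) {
  tree <- as_phylou_tree_keep_scale(tree)
  kind <- spec_kind_code(spec)
  alpha <- params$alpha
  if (is.null(alpha)) alpha <- half_life_to_alpha(params$t_half)
  v <- params$v
  if (is.null(v) || v < 0) stop("params$v (stationary variance) required")
  st <- shared_times(tree)
  V <- cpp_ou_covariance(alpha, max(v, 0), st$s, st$d)
  if (kind == 2) {
    if (!is_ultrametric(tree))
      stop("the adaptive model requires an ultrametric tree")
    s2x <- params$sigma2_x
    if (is.null(s2x)) stop("params$sigma2_x required for the adaptive model")
    K <- length(painting$regime_names)
    treg <- tip_regimes(tree, painting)
    bt <- if (spec$slopes == "by_regime") rep(params$beta, length.out = K)[treg]
          else rep(params$beta[1], n_tips(tree))
    Tdep <- max(tip_depths(tree))
    V <- V + s2x * (outer(bt, bt) * cpp_adaptive_kernel(alpha, st$s, Tdep))
  }
  if (!is.null(se_y)) {
    se_y <- rep(se_y, length.out = n_tips(tree))
    V <- V + diag(se_y^2, n_tips(tree))
  }
  V <- V + diag(1e-10 * max(v, 1e-12), n_tips(tree))
  ev_min <- NULL
  if (anyNA(V)) stop("covariance assembly produced NA")
  dimnames(V) <- list(tip_labels(tree), tip_labels(tree))
  V
}

# number of slope parameters implied by spec and data
spec_n_beta <- function(spec, K, P) {
  if (spec_kind_code(spec) == 0) return(0L)
  if (spec$slopes == "by_regime") K else P
}

# assemble the data list consumed by the C++ model
build_model_data <- function(tree, painting, spec, priors, y, se_y = NULL,
                             X = NULL, se_x = NULL) {
  N <- n_tips(tree)
  K <- length(painting$regime_names)
  kind <- spec_kind_code(spec)
  ml <- spec_ml_code(spec)
  if (kind == 0) { X <- NULL; se_x <- NULL }   # regimes-only model
  P <- if (is.null(X)) 0L else ncol(as.matrix(X))
  if (kind > 0 && P < 1) stop(spec$kind, " requires at least one predictor")
  if (kind == 2 && P != 1)
    stop("the adaptive model supports exactly one continuous predictor")
  if (spec$slopes == "by_regime" && P != 1)
    stop("by-regime slopes require exactly one predictor")
  if (ml == 2 && K < 2) stop("varying_effects requires at least 2 regimes")
  if (kind == 2 && !is_ultrametric(tree))
    stop("the adaptive model requires an ultrametric tree")

  st <- shared_times(tree)
  seg <- painting_segments(tree, painting)
  depths <- unname(tip_depths(tree))

  me_y <- switch(spec$me_response,
                 none = FALSE, latent = TRUE, auto = !is.null(se_y))
  if (me_y && is.null(se_y))
    stop("me_response = 'latent' requires response standard errors")
  latent_x <- switch(spec$me_predictors,
                     none = FALSE, latent = TRUE, auto = !is.null(se_x))
  if (latent_x && (is.null(se_x) || P == 0))
    stop("me_predictors = 'latent' requires predictor standard errors")

  Xm <- if (P > 0) as.matrix(X) else matrix(0, N, 1)
  sxm <- if (latent_x) as.matrix(se_x) else matrix(0, N, max(P, 1))
  if (latent_x && any(sxm <= 0))
    stop("latent predictor measurement error requires strictly positive SEs")

  est_x <- kind == 2 && spec$sigma2_x == "estimate"
  sigma2x_fix <- 1; mux_fix <- 0
  if (kind == 2 && !est_x) {
    Si <- solve(st$s + diag(1e-10, N))
    one <- rep(1, N)
    mux_fix <- as.numeric((one %*% Si %*% Xm[, 1]) / (one %*% Si %*% one))
    sigma2x_fix <- max(as.numeric(t(Xm[, 1] - mux_fix) %*% Si %*%
                                    (Xm[, 1] - mux_fix)) / N, 1e-8)
  }

  n_beta <- spec_n_beta(spec, K, P)
  list(N = N, K = K, P = P, kind = kind, ml = ml,
       noncentered = spec$parameterization == "noncentered",
       by_regime = spec$slopes == "by_regime",
       est_x = est_x, latent_x = latent_x, me_y = me_y,
       y = as.numeric(y),
       se2_y = if (me_y) rep(se_y, length.out = N)^2 else rep(0, N),
       depths = depths, X = Xm, se_x = sxm,
       s = unname(st$s), d = unname(st$d),
       seg_tip = seg$seg_tip, seg_reg = seg$seg_reg,
       seg_ta = seg$seg_ta, seg_tb = seg$seg_tb,
       tip_reg = tip_regimes(tree, painting) - 1L,
       root_reg = seg$root_reg,
       T = max(depths),
       sigma2x_fix = sigma2x_fix, mux_fix = mux_fix,
       jitter_rel = 1e-10,
       lat_sd_mult = priors$latent_sd_mult,
       priors = encode_priors(priors, K, max(n_beta, 1)))
}

# unconstrained parameter names in C++ layout order
model_par_names <- function(dat) {
  nm <- c("log_t_half", "log_v")
  if (dat$kind == 2 && dat$est_x) nm <- c(nm, "log_sigma2_x", "mu_x")
  tnm <- if (dat$ml >= 1 && dat$noncentered) "z_theta" else "theta"
  nm <- c(nm, sprintf("%s[%d]", tnm, seq_len(dat$K)))
  if (dat$ml >= 1) nm <- c(nm, "theta_bar", "log_sigma_theta")
  if (dat$kind > 0) {
    n_beta <- if (dat$by_regime) dat$K else dat$P
    bnm <- if (dat$ml == 2 && dat$noncentered) "z_beta" else "beta"
    nm <- c(nm, sprintf("%s[%d]", bnm, seq_len(n_beta)))
    if (dat$ml == 2) nm <- c(nm, "beta_bar", "log_sigma_beta", "atanh_rho")
  }
  if (dat$latent_x && dat$P > 0)
    nm <- c(nm, sprintf("z_x[%d,%d]",
                        rep(seq_len(dat$N), dat$P),
                        rep(seq_len(dat$P), each = dat$N)))
  nm
}

# data-informed initial point on the unconstrained scale; jitter in [-1, 1]
# scaled by `mag` (R RNG; caller seeds per chain)
model_init <- function(dat, priors, mag = 0.5) {
  jit <- function(n = 1) runif(n, -1, 1) * mag
  q <- c(priors$t_half$meanlog + jit() * priors$t_half$sdlog,
         log(max(var(dat$y), 1e-6)) / 1 + jit())
  if (dat$kind == 2 && dat$est_x)
    q <- c(q, priors$sigma2_x$meanlog + jit(), priors$mu_x$mean + jit())
  my <- mean(dat$y)
  if (dat$ml >= 1 && dat$noncentered) {
    q <- c(q, jit(dat$K) * 0.2, my + jit(), log(0.5) + jit())
  } else if (dat$ml >= 1) {
    q <- c(q, my + jit(dat$K), my + jit(), log(0.5) + jit())
  } else {
    q <- c(q, my + jit(dat$K))
  }
  if (dat$kind > 0) {
    n_beta <- if (dat$by_regime) dat$K else dat$P
    bm <- if (is.null(priors$beta$mean)) 0 else priors$beta$mean[1]
    if (dat$ml == 2 && dat$noncentered) {
      q <- c(q, jit(n_beta) * 0.2, bm + jit() * 0.2, log(0.3) + jit(), jit() * 0.3)
    } else if (dat$ml == 2) {
      q <- c(q, bm + jit(n_beta) * 0.2, bm + jit() * 0.2, log(0.3) + jit(),
             jit() * 0.3)
    } else {
      q <- c(q, bm + jit(n_beta) * 0.2)
    }
  }
  if (dat$latent_x && dat$P > 0) q <- c(q, jit(dat$N * dat$P) * 0.1)
  q
}
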