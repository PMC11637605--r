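# Prior construction.  The defaults implement the package's guidelines for
# biologically meaningful priors on the unit-height tree scale:
#  * t_half ~ lognormal with 10th percentile at 10% of tree height and 90th
#    percentile at one tree height (spans near-instantaneous adaptation to
#    near-Brownian motion);
#  * v ~ exponential with prior mean equal to the sample variance of Y
#    (uniform[0, 4 var(Y)] and half-Cauchy(var(Y)) available);
#  * theta ~ normal centered at mean(Y), sd 1 (overridable);
#  * slopes ~ normal centered on the OLS slope;
#  * multilevel hyperpriors: hypermeans as above, scales ~ Exponential(1),
#    2x2 intercept/slope correlation ~ LKJ(4).

#' Construct the default prior set from the data
#'
#' @param tree A `phylou_tree` (used for its height scale; priors are defined
#'   on the unit-height scale used for fitting).
#' @param y Response values.
#' @param X Optional predictor matrix/vector (required for models with
#'   continuous predictors).
#' @param theta_sd Prior SD for optima (guideline default 1).
#' @param t_half_quantiles Lower/upper 10% anchor points of the half-life
#'   prior on the unit-height scale.
#' @param v_prior Type of stationary-variance prior.
#' @return An object of class `phylou_priors`; every element can be
#'   overridden by assignment before fitting.
#' @export
default_priors <- function(tree, y, X = NULL, theta_sd = 1,
                           t_half_quantiles = c(0.1, 1.0),
                           v_prior = c("exponential", "halfcauchy", "uniform")) {
  v_prior <- match.arg(v_prior)
  if (length(y) < 3) stop("need at least 3 species to construct default priors")
  lo <- t_half_quantiles[1]; hi <- t_half_quantiles[2]
  if (!(lo > 0 && hi > lo)) stop("invalid t_half_quantiles")
  meanlog <- (log(lo) + log(hi)) / 2
  sdlog <- (log(hi) - log(lo)) / (2 * qnorm(0.9))
  vy <- var(y)
  vpar <- switch(v_prior,
                 exponential = list(type = "exponential", par = c(1 / vy, 0)),
                 halfcauchy = list(type = "halfcauchy", par = c(vy, 0)),
                 uniform = list(type = "uniform", par = c(0, 4 * vy)))
  beta_mean <- NULL; beta_sd <- NULL
  s2x_meanlog <- 0; mux <- c(0, 1)
  if (!is.null(X)) {
    X <- as.matrix(X)
    for (j in seq_len(ncol(X))) {
      if (sd(X[, j]) == 0)
        stop("predictor ", j, " is constant: the OLS slope prior is undefined")
    }
    b_ols <- as.numeric(coef(lm(y ~ X))[-1])
    beta_mean <- b_ols
    beta_sd <- pmax(0.25, sd(y) / apply(X, 2, sd))
    # plug-in BM rate of the first predictor (adaptive-model prior center)
    st <- shared_times(as_phylou_tree_keep_scale(tree))
    Si <- solve(st$s + diag(1e-10, nrow(st$s)))
    one <- rep(1, nrow(st$s))
    muhat <- as.numeric((one %*% Si %*% X[, 1]) / (one %*% Si %*% one))
    s2hat <- as.numeric(t(X[, 1] - muhat) %*% Si %*% (X[, 1] - muhat)) / nrow(st$s)
    s2x_meanlog <- log(max(s2hat, 1e-8))
    mux <- c(mean(X[, 1]), max(sd(X[, 1]), 1e-6))
  }
  structure(list(
    t_half = list(meanlog = meanlog, sdlog = sdlog),
    v = vpar,
    theta = list(mean = mean(y), sd = theta_sd),
    beta = list(mean = beta_mean, sd = beta_sd),
    theta_bar = list(mean = mean(y), sd = theta_sd),
    sigma_theta = list(rate = 1),
    beta_bar = list(mean = if (is.null(beta_mean)) 0 else beta_mean[1],
                    sd = if (is.null(beta_sd)) 0.25 else beta_sd[1]),
    sigma_beta = list(rate = 1),
    rho = list(eta = 4),
    sigma2_x = list(meanlog = s2x_meanlog, sdlog = 1),
    mu_x = list(mean = mux[1], sd = mux[2]),
    latent_sd_mult = 10),
    class = "phylou_priors")
}

#' Priors used for the simulation-study workflow
#'
#' The example prior set of the multilevel model blocks:
#' `t_half ~ logNormal(log 0.25, 0.25)`, `v ~ Exponential(20)`,
#' `theta_bar ~ Normal(0, 1)`, `beta_bar ~ Normal(0, 0.25)`,
#' `sigma_theta, sigma_beta ~ Exponential(1)`, `Rho ~ LKJ(4)`; non-pooled
#' optima/slopes get the corresponding fixed normal priors.
#'
#' @return A `phylou_priors` object.
#' @export
sim_study_priors <- function() {
  structure(list(
    t_half = list(meanlog = log(0.25), sdlog = 0.25),
    v = list(type = "exponential", par = c(20, 0)),
    theta = list(mean = 0, sd = 1),
    beta = list(mean = 0, sd = 0.25),
    theta_bar = list(mean = 0, sd = 1),
    sigma_theta = list(rate = 1),
    beta_bar = list(mean = 0, sd = 0.25),
    sigma_beta = list(rate = 1),
    rho = list(eta = 4),
    sigma2_x = list(meanlog = 0, sdlog = 1),
    mu_x = list(mean = 0, sd = 1),
    latent_sd_mult = 10),
    class = "phylou_priors")
}

#' @export
print.phylou_priors <- function(x, ...) {
  cat("phylou_priors:\n")
  cat(sprintf("  t_half ~ logNormal(%.4g, %.4g)\n", x$t_half$meanlog, x$t_half$sdlog))
  cat(sprintf("  v ~ %s(%s)\n", x$v$type,
              paste(signif(x$v$par[x$v$par != 0 | seq_along(x$v$par) == 1], 4),
                    collapse = ", ")))
  cat(sprintf("  theta ~ Normal(%s, %s)\n",
              paste(signif(x$theta$mean, 4), collapse = ","),
              paste(signif(x$theta$sd, 4), collapse = ",")))
  if (!is.null(x$beta$mean))
    cat(sprintf("  beta ~ Normal(%s, %s)\n",
                paste(signif(x$beta$mean, 4), collapse = ","),
                paste(signif(x$beta$sd, 4), collapse = ",")))
  cat(sprintf("  hyper: theta_bar ~ N(%.3g, %.3g), sigma_theta ~ Exp(%.3g), Rho ~ LKJ(%.3g)\n",
              x$theta_bar$mean, x$theta_bar$sd, x$sigma_theta$rate, x$rho$eta))
  invisible(x)
}

# encode a phylou_priors object for the C++ model (K regimes, n_beta slopes)
encode_priors <- function(priors, K, n_beta) {
  rec <- function(m, s, n) {
    m <- rep(if (is.null(m)) 0 else m, length.out = n)
    s <- rep(if (is.null(s)) 1 else s, length.out = n)
    cbind(m, s)
  }
  vtype <- match(priors$v$type, c("exponential", "halfcauchy", "uniform")) - 1L
  list(lt = c(priors$t_half$meanlog, priors$t_half$sdlog),
       vtype = vtype,
       v = as.numeric(priors$v$par),
       theta = rec(priors$theta$mean, priors$theta$sd, max(K, 1)),
       beta = rec(priors$beta$mean, priors$beta$sd, max(n_beta, 1)),
       tbar = c(priors$theta_bar$mean, priors$theta_bar$sd),
       st_rate = priors$sigma_theta$rate,
       bbar = c(priors$beta_bar$mean, priors$beta_bar$sd),
       sb_rate = priors$sigma_beta$rate,
       lkj_eta = priors$rho$eta,
       ls2x = c(priors$sigma2_x$meanlog, priors$sigma2_x$sdlog),
       mux = c(priors$mu_x$mean, priors$mu_x$sd))
}

# draw one parameter set from the prior (R-side RNG; used by prior
# predictive checks and prior-sampling tests)
sample_prior <- function(priors, spec, K, n_beta) {
  ml <- spec_ml_code(spec)
  kind <- spec_kind_code(spec)
  t_half <- rlnorm(1, priors$t_half$meanlog, priors$t_half$sdlog)
  v <- switch(priors$v$type,
              exponential = rexp(1, priors$v$par[1]),
              halfcauchy = abs(priors$v$par[1] * tan(pi * runif(1) / 2)),
              uniform = runif(1, priors$v$par[1], priors$v$par[2]))
  out <- list(t_half = t_half, v = v)
  if (ml == 0) {
    out$theta <- rnorm(K, rep(priors$theta$mean, length.out = K),
                       rep(priors$theta$sd, length.out = K))
    if (kind > 0)
      out$beta <- rnorm(n_beta, rep(priors$beta$mean, length.out = n_beta),
                        rep(priors$beta$sd, length.out = n_beta))
  } else {
    tbar <- rnorm(1, priors$theta_bar$mean, priors$theta_bar$sd)
    st <- rexp(1, priors$sigma_theta$rate)
    out$theta_bar <- tbar; out$sigma_theta <- st
    if (ml == 1) {
      out$theta <- rnorm(K, tbar, st)
      if (kind > 0)
        out$beta <- rnorm(n_beta, rep(priors$beta$mean, length.out = n_beta),
                          rep(priors$beta$sd, length.out = n_beta))
    } else {
      bbar <- rnorm(1, priors$beta_bar$mean, priors$beta_bar$sd)
      sb <- rexp(1, priors$sigma_beta$rate)
      r <- lkj2_sample(priors$rho$eta)
      zt <- rnorm(K); zb <- rnorm(K)
      out$beta_bar <- bbar; out$sigma_beta <- sb; out$rho_cor <- r
      out$theta <- tbar + st * zt
      out$beta <- bbar + sb * (r * zt + sqrt(1 - r^2) * zb)
    }
  }
  if (kind == 2) {
    out$sigma2_x <- rlnorm(1, priors$sigma2_x$meanlog, priors$sigma2_x$sdlog)
    out$mu_x <- rnorm(1, priors$mu_x$mean, priors$mu_x$sd)
  }
  out
}

# 2x2 LKJ correlation draw: (1 + r)/2 ~ Beta(eta, eta)
lkj2_sample <- function(eta) 2 * rbeta(1, eta, eta) - 1

#' @importFrom stats rbeta
NULL
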