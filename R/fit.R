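# Posterior sampling for OU models: data preparation, NUTS runs across
# chains, draw management, derived quantities, and summaries.

#' Fit a Bayesian OU model
#'
#' Runs the built-in No-U-Turn sampler on the selected model.  The tree is
#' rescaled to unit height internally (half-lives are reported both on that
#' scale and back-transformed through `scale_factor`); predictors are
#' mean-centered internally so optima/intercepts are reported at the average
#' interspecific predictor value.
#'
#' @param tree A `phylou_tree` (or ape `phylo`).
#' @param traits Data frame with a `species` column matching the tip labels
#'   (exact match after whitespace trimming), the response, optional
#'   `<var>_se` standard-error columns, predictors, and optionally a regime
#'   column.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names (at most one
#'   for adaptive / by-regime-slope models).
#' @param painting A `phylou_painting`; if `NULL` and `regimes` is given,
#'   ancestral regimes are reconstructed with [mk_painting()] (ER/SYM/ARD +
#'   AIC selection); if both are `NULL` a single-regime painting is used.
#' @param regimes Name of a tip-regime column in `traits`.
#' @param spec A [ou_model_spec()].
#' @param priors A [default_priors()]-style object (constructed from the data
#'   when `NULL`).
#' @param chains,iter,warmup Sampler settings (defaults: 2 chains of 4000
#'   iterations, half warmup).
#' @param seed Integer seed; fits are reproducible bit-for-bit on the same
#'   platform.
#' @param adapt_delta,max_treedepth NUTS tuning.
#' @param pointwise Pointwise log-likelihood decomposition stored with the
#'   fit: `"conditional"` (leave-one-out conditional normal; default because
#'   residuals are phylogenetically correlated), `"marginal"`, or `"none"`.
#' @param quiet Suppress progress messages.
#' @return An object of class `phylou_fit`.
#' @export
ou_fit <- function(tree, traits, response, predictors = NULL, painting = NULL,
                   regimes = NULL, spec = ou_model_spec(), priors = NULL,
                   chains = 2, iter = 4000, warmup = floor(iter / 2), seed = 1,
                   adapt_delta = 0.8, max_treedepth = 10,
                   pointwise = c("conditional", "marginal", "none"),
                   quiet = FALSE) {
  pointwise <- match.arg(pointwise)
  tree <- as_phylou_tree_keep_scale(tree)
  tree <- scale_to_unit_height(tree)

  traits <- check_traits(tree, traits, response, predictors, regimes)
  y <- traits[[response]]
  se_y <- traits[[paste0(response, "_se")]]
  X <- NULL; se_x <- NULL
  if (length(predictors)) {
    X <- as.matrix(traits[predictors])
    se_cols <- paste0(predictors, "_se")
    if (all(se_cols %in% names(traits))) se_x <- as.matrix(traits[se_cols])
  }

  mk_info <- NULL
  if (is.null(painting)) {
    if (!is.null(regimes)) {
      tip_states <- setNames(as.character(traits[[regimes]]), traits$species)
      if (length(unique(tip_states)) == 1) {
        painting <- single_regime_painting(tree, unique(tip_states))
      } else {
        mkp <- mk_painting(tree, tip_states, seed = seed)
        painting <- mkp$painting
        mk_info <- mkp[c("mk", "aic_table")]
        if (!quiet)
          message("regimes reconstructed by Mk (", mkp$mk$rate_model,
                  " selected by AIC)")
      }
    } else {
      painting <- single_regime_painting(tree, "opt")
    }
  } else {
    # recompute lineages on the unit-height scale
    painting$tip_lineages <- compute_tip_lineages(tree, painting)
  }

  centers <- NULL
  if (!is.null(X)) {
    centers <- colMeans(X)
    X <- sweep(X, 2, centers)
  }
  if (is.null(priors)) priors <- default_priors(tree, y, X)

  dat <- build_model_data(tree, painting, spec, priors, y, se_y, X, se_x)
  xp <- ou_model_build(dat)
  par_names <- model_par_names(dat)

  # sanity: finite at the prior-median (unjittered) point
  q0 <- local({ set.seed(seed); model_init(dat, priors, mag = 0) })
  lp0 <- ou_model_logpost(xp, q0)
  if (!is.finite(lp0))
    stop("log posterior is not finite at the prior median; parameters: ",
         paste(sprintf("%s=%.3g", par_names, q0), collapse = ", "))

  keep <- iter - warmup
  if (keep < 2) stop("iter must exceed warmup by at least 2")
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed((as.numeric(seed) + 7919 * ch) %% 2147483629)
    init <- model_init(dat, priors, mag = 0.5)
    runs[[ch]] <- nuts_sample_cpp(xp, NULL, NULL, init, iter, warmup,
                                  adapt_delta, max_treedepth,
                                  chain_seed(seed, ch))
    if (!quiet)
      message(sprintf("chain %d: %d/%d divergent, step size %.3g", ch,
                      sum(runs[[ch]]$divergent), keep, runs[[ch]]$step_size))
  }

  unc <- array(NA_real_, c(keep, chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  lp <- matrix(NA_real_, keep, chains)
  divergent <- matrix(0L, keep, chains)
  for (ch in seq_len(chains)) {
    unc[, ch, ] <- runs[[ch]]$draws
    lp[, ch] <- runs[[ch]]$lp
    divergent[, ch] <- runs[[ch]]$divergent
  }

  ndiv <- sum(divergent)
  if (ndiv > 0.1 * keep * chains)
    warning(sprintf(paste0(
      "%d of %d post-warmup transitions were divergent; consider switching ",
      "to a non-centered parameterization or raising adapt_delta"),
      ndiv, keep * chains))

  const <- constrain_draws(xp, dat, unc, tree$scale_factor)

  fit <- structure(list(
    spec = spec, priors = priors, tree = tree, painting = painting,
    traits = traits, response = response, predictors = predictors,
    centers = centers, model_data = dat, par_names = par_names,
    draws = const$draws, unc_draws = unc, lp = lp, divergent = divergent,
    sampler = list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                   adapt_delta = adapt_delta, max_treedepth = max_treedepth,
                   step_size = vapply(runs, `[[`, 1.0, "step_size"),
                   n_divergent = ndiv,
                   me_mode = c(response = if (dat$me_y) "latent (marginalized)"
                                          else "none",
                               predictors = if (dat$latent_x) "latent"
                                            else "none")),
    mk_info = mk_info, pointwise_mode = pointwise), class = "phylou_fit")

  fit$diagnostics <- diagnostics(fit)
  if (pointwise != "none") fit$pointwise <- pointwise_loglik(fit, pointwise)
  fit
}

# validate and order the trait table against the tree
check_traits <- function(tree, traits, response, predictors = NULL,
                         regimes = NULL) {
  if (!is.data.frame(traits)) stop("'traits' must be a data frame")
  if (!"species" %in% names(traits)) stop("traits must have a 'species' column")
  traits$species <- trimws(as.character(traits$species))
  need <- c(response, predictors, regimes)
  missing_cols <- setdiff(need, names(traits))
  if (length(missing_cols))
    stop("missing trait column(s): ", paste(missing_cols, collapse = ", "))
  tips <- tip_labels(tree)
  miss <- setdiff(tips, traits$species)
  if (length(miss))
    stop("species in the tree but not the trait table: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(traits$species, tips)
  if (length(extra))
    stop("species in the trait table but not the tree: ",
         paste(extra, collapse = ", "))
  traits <- traits[match(tips, traits$species), , drop = FALSE]
  for (cl in c(response, predictors))
    if (anyNA(traits[[cl]])) stop("NA values in column '", cl, "'")
  rownames(traits) <- NULL
  traits
}

# painting with a single regime covering the whole tree
single_regime_painting <- function(tree, name = "opt") {
  labs <- node_labels(tree)
  paint_regimes(tree, setNames(name, labs[root_node(tree)]),
                regime_names = name)
}

# map unconstrained draw array -> named constrained array (plus derived
# quantities: evolutionary slopes, half-life in original time units)
constrain_draws <- function(xp, dat, unc, scale_factor) {
  keep <- dim(unc)[1]; chains <- dim(unc)[2]
  ex <- ou_model_constrain(xp, unc[1, 1, ])
  nms <- c("t_half", "v", "sigma2_y", sprintf("theta[%d]", seq_len(dat$K)))
  if (dat$kind > 0) {
    nb <- length(ex$beta)
    nms <- c(nms, sprintf("beta[%d]", seq_len(nb)))
    if (dat$kind == 2) nms <- c(nms, sprintf("beta_evol[%d]", seq_len(nb)))
  }
  if (dat$ml >= 1) nms <- c(nms, "theta_bar", "sigma_theta")
  if (dat$ml == 2) nms <- c(nms, "beta_bar", "sigma_beta", "Rho")
  if (dat$kind == 2) nms <- c(nms, "sigma2_x", "mu_x")
  nms <- c(nms, "t_half_original")
  out <- array(NA_real_, c(keep, chains, length(nms)),
               dimnames = list(NULL, NULL, nms))
  Tdep <- dat$T
  for (ch in seq_len(chains)) {
    for (s in seq_len(keep)) {
      p <- ou_model_constrain(xp, unc[s, ch, ])
      row <- c(p$t_half, p$v, p$sigma2_y, p$theta)
      if (dat$kind > 0) {
        row <- c(row, p$beta)
        if (dat$kind == 2)
          row <- c(row, p$beta * cpp_rho_factor(p$alpha * Tdep))
      }
      if (dat$ml >= 1) row <- c(row, p$theta_bar, p$sigma_theta)
      if (dat$ml == 2) row <- c(row, p$beta_bar, p$sigma_beta, p$rho_cor)
      if (dat$kind == 2) row <- c(row, p$sigma2_x, p$mu_x)
      row <- c(row, p$t_half * scale_factor)
      out[s, ch, ] <- row
    }
  }
  list(draws = out)
}

#' @export
print.phylou_fit <- function(x, ...) {
  cat(sprintf("phylou_fit: %s (%s, %s)\n", x$spec$kind, x$spec$multilevel,
              x$spec$parameterization))
  cat(sprintf("  %d species, %d regimes; %d chains x %d iterations (%d warmup)\n",
              x$model_data$N, x$model_data$K, x$sampler$chains,
              x$sampler$iter, x$sampler$warmup))
  cat(sprintf("  divergent transitions: %d; max R-hat %.3f; min n_eff %.0f\n",
              x$sampler$n_divergent, max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$n_eff, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary table
#'
#' One row per parameter: posterior mean, 95% compatibility interval, SD,
#' effective sample size and split R-hat, with a flag when `R-hat >= 1.1` or
#' `n_eff < 100`.
#'
#' @param object A `phylou_fit`.
#' @param prob Interval probability (default 0.95).
#' @param ... Unused.
#' @return A data.frame.
#' @export
summary.phylou_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  dn <- dimnames(object$draws)[[3]]
  dg <- object$diagnostics
  rows <- lapply(seq_along(dn), function(j) {
    x <- as.numeric(object$draws[, , j])
    data.frame(parameter = dn[j], mean = mean(x),
               ci_lower = quantile(x, a, names = FALSE),
               ci_upper = quantile(x, 1 - a, names = FALSE),
               sd = sd(x),
               n_eff = dg$n_eff[match(dn[j], dg$parameter)],
               rhat = dg$rhat[match(dn[j], dg$parameter)])
  })
  out <- do.call(rbind, rows)
  out$flag <- ifelse(!is.na(out$rhat) & (out$rhat >= 1.1 | out$n_eff < 100),
                     "*", "")
  out
}

# rebuild the C++ model object of a fit (external pointers do not persist)
fit_model_xp <- function(fit) ou_model_build(fit$model_data)

#' Unnormalized log posterior of a fitted model
#'
#' Returns a function over the unconstrained parameter vector (all
#' normalizing constants and Jacobians included) — the target used by the
#' sampler and by bridge sampling.
#'
#' @param fit A `phylou_fit`.
#' @return `function(q) -> numeric`.
#' @export
log_posterior_fn <- function(fit) {
  xp <- fit_model_xp(fit)
  function(q) ou_model_logpost(xp, q)
}

# flattened (draws*chains) x npar matrix of unconstrained draws
flat_unc_draws <- function(fit) {
  d <- fit$unc_draws
  matrix(aperm(d, c(1, 2, 3)), dim(d)[1] * dim(d)[2], dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}
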