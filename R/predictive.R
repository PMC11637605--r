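# Prior and posterior predictive checks: replicate datasets from parameter
# draws (prior or posterior) through the generative simulator, summarize
# them against the observed data, and compute a pointwise band-coverage
# statistic.

#' Prior predictive simulation
#'
#' Generates replicated datasets using only the prior distributions —
#' equivalent to running the model without data.  Useful to judge whether
#' priors put mass on scientifically plausible data.
#'
#' @param tree A `phylou_tree`.
#' @param painting A `phylou_painting`.
#' @param spec A `phylou_spec`.
#' @param priors A `phylou_priors`.
#' @param X Predictor values (required for predictor models; no response
#'   data is needed).
#' @param n_draws Number of replicated datasets (default 200).
#' @param seed Integer seed.
#' @return Object of class `phylou_ppc` with `y_rep` (n_draws x N), the
#'   parameter draws, and `observed = NULL`.
#' @export
prior_predictive <- function(tree, painting, spec, priors, X = NULL,
                             n_draws = 200, seed = 1) {
  tree <- as_phylou_tree_keep_scale(tree)
  K <- length(painting$regime_names)
  P <- if (is.null(X)) 0L else 1L
  n_beta <- spec_n_beta(spec, K, max(P, 1L))
  if (spec_kind_code(spec) > 0 && is.null(X))
    stop("predictor values are required for ", spec$kind)
  y_rep <- matrix(NA_real_, n_draws, n_tips(tree))
  colnames(y_rep) <- tip_labels(tree)
  pars <- vector("list", n_draws)
  for (s in seq_len(n_draws)) {
    set.seed(derive_seed(seed, 2L * s))
    p <- sample_prior(priors, spec, K, n_beta)
    pars[[s]] <- p
    y_rep[s, ] <- simulate_response(tree, painting, spec, p, X = X,
                                    seed = derive_seed(seed, 2L * s + 1L))
  }
  structure(list(y_rep = y_rep, params = pars, observed = NULL,
                 mode = "prior"), class = "phylou_ppc")
}

#' Posterior predictive simulation
#'
#' Replicates datasets from posterior parameter draws through the generative
#' model and stores the observed response for comparison.
#'
#' @param fit A `phylou_fit`.
#' @param n_draws Number of replicated datasets (default 200).
#' @param seed Integer seed.
#' @return A `phylou_ppc` with `observed` set.
#' @export
posterior_predictive <- function(fit, n_draws = 200, seed = 1) {
  draws <- fit$draws
  S <- dim(draws)[1] * dim(draws)[2]
  flat <- matrix(draws, S, dim(draws)[3],
                 dimnames = list(NULL, dimnames(draws)[[3]]))
  set.seed(derive_seed(seed, 0))
  idx <- sample.int(S, n_draws, replace = n_draws > S)
  K <- fit$model_data$K
  Xc <- NULL
  if (length(fit$predictors))
    Xc <- sweep(as.matrix(fit$traits[fit$predictors]), 2, fit$centers)
  y_rep <- matrix(NA_real_, n_draws, fit$model_data$N)
  colnames(y_rep) <- tip_labels(fit$tree)
  pars <- vector("list", n_draws)
  for (s in seq_len(n_draws)) {
    row <- flat[idx[s], ]
    p <- list(t_half = row[["t_half"]], v = row[["v"]],
              theta = unname(row[sprintf("theta[%d]", seq_len(K))]))
    bn <- grep("^beta\\[", names(row), value = TRUE)
    if (length(bn)) p$beta <- unname(row[bn])
    if ("sigma2_x" %in% names(row)) p$sigma2_x <- row[["sigma2_x"]]
    pars[[s]] <- p
    y_rep[s, ] <- simulate_response(fit$tree, fit$painting, fit$spec, p,
                                    X = Xc, seed = derive_seed(seed, s))
  }
  structure(list(y_rep = y_rep, params = pars,
                 observed = setNames(fit$model_data$y, tip_labels(fit$tree)),
                 mode = "posterior"), class = "phylou_ppc")
}

#' Pointwise band coverage of a predictive check
#'
#' Fraction of observed values lying inside the central `level` band of
#' their replicated values.  A well-calibrated posterior predictive check
#' should cover most observations; for prior checks a high coverage means
#' the priors span the data.
#'
#' @param ppc A `phylou_ppc`.
#' @param observed Observed values (taken from the ppc if present).
#' @param level Band probability (default 0.99).
#' @return Scalar coverage in `[0, 1]`.
#' @export
ppc_coverage <- function(ppc, observed = NULL, level = 0.99) {
  if (is.null(observed)) observed <- ppc$observed
  if (is.null(observed)) stop("observed values required")
  a <- (1 - level) / 2
  lo <- apply(ppc$y_rep, 2, quantile, probs = a)
  hi <- apply(ppc$y_rep, 2, quantile, probs = 1 - a)
  mean(observed >= lo & observed <= hi)
}

#' Summary statistics of replicated datasets
#' @param object A `phylou_ppc`.
#' @param ... Unused.
#' @return Data frame of per-replicate mean, sd, min, max, plus the observed
#'   row when available.
#' @export
summary.phylou_ppc <- function(object, ...) {
  stats <- data.frame(
    replicate = seq_len(nrow(object$y_rep)),
    mean = rowMeans(object$y_rep),
    sd = apply(object$y_rep, 1, sd),
    min = apply(object$y_rep, 1, min),
    max = apply(object$y_rep, 1, max))
  attr(stats, "observed") <-
    if (!is.null(object$observed))
      c(mean = mean(object$observed), sd = sd(object$observed),
        min = min(object$observed), max = max(object$observed))
  stats
}

#' @export
print.phylou_ppc <- function(x, ...) {
  cat(sprintf("phylou_ppc (%s): %d replicates x %d species\n", x$mode,
              nrow(x$y_rep), ncol(x$y_rep)))
  if (!is.null(x$observed))
    cat(sprintf("  99%% band coverage of observed: %.3f\n", ppc_coverage(x)))
  invisible(x)
}

#' Predictive-check overlay figure
#'
#' Density overlay of replicated datasets (gray) against the observed data
#' (black), written to a PNG when `file` is given.
#'
#' @param x A `phylou_ppc`.
#' @param file Optional PNG path.
#' @param max_lines Number of replicate densities to draw.
#' @param ... Unused.
#' @return Invisibly, the file path (or NULL).
#' @export
plot.phylou_ppc <- function(x, file = NULL, max_lines = 100, ...) {
  if (!is.null(file)) png(file, width = 800, height = 600)
  dens <- apply(x$y_rep[seq_len(min(nrow(x$y_rep), max_lines)), , drop = FALSE],
                1, stats::density)
  xl <- range(vapply(dens, function(d) range(d$x), numeric(2)))
  yl <- c(0, max(vapply(dens, function(d) max(d$y), 1.0)))
  plot(NA, xlim = xl, ylim = yl, xlab = "response", ylab = "density",
       main = sprintf("%s predictive check", x$mode))
  for (d in dens) lines(d, col = grDevices::adjustcolor("gray40", 0.25))
  if (!is.null(x$observed)) lines(stats::density(x$observed), lwd = 2)
  if (!is.null(file)) { dev.off(); return(invisible(file)) }
  invisible(NULL)
}
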