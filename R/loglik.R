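# Pointwise log-likelihood decompositions of the multivariate-normal model,
# per posterior draw.  Because residuals are phylogenetically correlated the
# default decomposition is the leave-one-out conditional normal (Schur
# complement via the precision matrix); the marginal decomposition (each
# species against its own marginal normal) is retained for speed and
# cross-checks.  Note the marginal entries do not sum to the joint
# log-likelihood when V has off-diagonal structure.

#' Pointwise log-likelihood matrix
#'
#' @param fit A `phylou_fit`.
#' @param mode `"conditional"`: entry (s, i) is the log density of `y_i`
#'   given all other observed responses under draw s's mean and covariance;
#'   `"marginal"`: the univariate normal density from `(mu_i, V_ii)`.
#' @param thin Keep every `thin`-th draw (default 1 = all).
#' @return Object of class `phylou_pll`: matrix (draws x species) with the
#'   decomposition mode as attribute `mode`.
#' @export
pointwise_loglik <- function(fit, mode = c("conditional", "marginal"), thin = 1) {
  mode <- match.arg(mode)
  xp <- fit_model_xp(fit)
  U <- flat_unc_draws(fit)
  idx <- seq(1, nrow(U), by = thin)
  y <- fit$model_data$y
  N <- length(y)
  out <- matrix(NA_real_, length(idx), N)
  colnames(out) <- tip_labels(fit$tree)
  for (r in seq_along(idx)) {
    mats <- ou_model_matrices(xp, U[idx[r], ])
    out[r, ] <- pointwise_loglik_one(y, as.numeric(mats$mu), mats$V, mode)
  }
  structure(out, mode = mode, class = c("phylou_pll", "matrix"))
}

# single-draw decomposition
pointwise_loglik_one <- function(y, mu, V, mode) {
  if (mode == "marginal") return(dnorm(y, mu, sqrt(diag(V)), log = TRUE))
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular covariance in conditional pointwise log-likelihood"))
  P <- chol2inv(ch)
  r <- y - mu
  Pr <- as.numeric(P %*% r)
  pii <- diag(P)
  if (any(pii <= 0)) stop("singular conditional variance")
  -0.5 * log(2 * pi) + 0.5 * log(pii) - 0.5 * Pr^2 / pii
}
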