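# Marginal likelihood by iterative bridge sampling with a moment-matched
# multivariate-normal proposal on the unconstrained scale, and Bayes factors
# as ratios of marginal likelihoods.  The estimator SE uses the standard
# relative-mean-square-error approximation treating draws as independent;
# with autocorrelated MCMC draws it is a lower bound, and Bayes factors from
# vague priors should be read conservatively.

#' Bridge-sampling estimate of the log marginal likelihood
#'
#' @param x A `phylou_fit`, or a matrix of posterior draws on the
#'   unconstrained scale (draws x parameters).
#' @param log_target For the matrix method: function returning the
#'   unnormalized log posterior (all constants included) at a parameter
#'   vector.
#' @param seed Seed for the proposal draws.
#' @param reltol Relative tolerance of the iterative scheme.
#' @param max_iter Iteration cap.
#' @param ... Passed to methods.
#' @return List with `log_marginal`, `se`, `n_iterations`, `converged`.
#' @export
bridge_log_marginal <- function(x, ...) UseMethod("bridge_log_marginal")

#' @rdname bridge_log_marginal
#' @export
bridge_log_marginal.phylou_fit <- function(x, seed = 1, ...) {
  bridge_log_marginal(flat_unc_draws(x), log_target = log_posterior_fn(x),
                      seed = seed, ...)
}

#' @rdname bridge_log_marginal
#' @export
bridge_log_marginal.default <- function(x, log_target, seed = 1,
                                        reltol = 1e-8, max_iter = 1000, ...) {
  draws <- as.matrix(x)
  S <- nrow(draws); d <- ncol(draws)
  if (S < 1000) stop("bridge sampling needs at least 1000 posterior draws")
  # split: first half fits the proposal, second half enters the estimator
  half <- floor(S / 2)
  fit_part <- draws[seq_len(half), , drop = FALSE]
  use_part <- draws[(half + 1):S, , drop = FALSE]
  m <- colMeans(fit_part)
  Sg <- cov(fit_part) + diag(1e-10, d)
  ch <- chol(Sg)
  ldet <- 2 * sum(log(diag(ch)))
  dprop <- function(Q) {
    Z <- forwardsolve(t(ch), t(Q) - m)
    -0.5 * colSums(Z^2) - 0.5 * ldet - 0.5 * d * log(2 * pi)
  }
  n1 <- nrow(use_part)
  n2 <- n1
  set.seed(seed)
  Zp <- matrix(rnorm(n2 * d), n2, d)
  prop <- sweep(Zp %*% ch, 2, m, "+")

  lt1 <- apply(use_part, 1, log_target)
  lt2 <- apply(prop, 1, log_target)
  if (!any(is.finite(lt2)))
    stop("proposal does not overlap the posterior (all proposal draws have ",
         "zero posterior density); more draws or a better-mixed chain needed")
  l1 <- lt1 - dprop(use_part)
  l2 <- lt2 - dprop(prop)
  l2[!is.finite(l2)] <- -Inf
  lstar <- median(l1[is.finite(l1)])
  e1 <- l1 - lstar; e2 <- l2 - lstar
  ls1 <- log(n1 / (n1 + n2)); ls2 <- log(n2 / (n1 + n2))

  logr <- 0
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    # num_j = e2_j - log(s1 e^{e2_j} + s2 r); den_i = -log(s1 e^{e1_i} + s2 r)
    den_terms <- -pair_logsumexp(ls1 + e1, ls2 + logr)
    num_terms <- e2 - pair_logsumexp(ls2 + logr, ls1 + e2)
    logr_new <- (logsumexp(num_terms) - log(n2)) -
                (logsumexp(den_terms) - log(n1))
    if (!is.finite(logr_new)) stop("bridge iteration diverged")
    if (abs(logr_new - logr) <= reltol * max(abs(logr_new), 1e-12)) {
      logr <- logr_new; converged <- TRUE; break
    }
    logr <- logr_new
  }
  log_ml <- logr + lstar

  # iid relative-MSE approximation (Fruhwirth-Schnatter 2004)
  r <- exp(logr)
  f1 <- exp(e1 - pair_logsumexp(ls1 + e1, ls2 + logr))      # p-part weights
  f2 <- exp(logr - pair_logsumexp(ls1 + e2, ls2 + logr))    # proposal part
  re2 <- var(f1) / (n1 * mean(f1)^2) + var(f2) / (n2 * mean(f2)^2)
  list(log_marginal = log_ml, se = sqrt(max(re2, 0)),
       n_iterations = it, converged = converged)
}

# elementwise log(exp(a) + exp(b)) for a vector and vector/scalar
pair_logsumexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

#' Bayes factor from two log marginal likelihoods
#'
#' `BF(a, b) = exp(lm_a - lm_b)`, the ratio of the probabilities of the
#' observed data under the two models.
#'
#' @param lm_a,lm_b Log marginal likelihoods (numbers or
#'   [bridge_log_marginal()] results).
#' @return List with `bf`, `log_bf`, and `se_log_bf` when the inputs carry
#'   estimator SEs.
#' @export
bayes_factor <- function(lm_a, lm_b) {
  se <- NULL
  if (is.list(lm_a) && is.list(lm_b))
    se <- sqrt(lm_a$se^2 + lm_b$se^2)
  la <- if (is.list(lm_a)) lm_a$log_marginal else lm_a
  lb <- if (is.list(lm_b)) lm_b$log_marginal else lm_b
  out <- list(log_bf = la - lb, bf = exp(la - lb), se_log_bf = se)
  class(out) <- "phylou_bf"
  out
}

#' @export
print.phylou_bf <- function(x, ...) {
  cat(sprintf("Bayes factor: %.4g (log BF %.4g%s)\n", x$bf, x$log_bf,
              if (!is.null(x$se_log_bf))
                sprintf(", SE of log BF %.3g", x$se_log_bf) else ""))
  cat("note: Bayes factors can be conservative under vague priors\n")
  invisible(x)
}
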