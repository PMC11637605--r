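# Approximate leave-one-out cross-validation by Pareto-smoothed importance
# sampling (PSIS), the widely applicable information criterion (WAIC), and
# pairwise predictive-accuracy comparison.  The PSIS recipe is the standard
# published one: tail size min(0.2 S, 3 sqrt(S)), generalized-Pareto fit to
# the tail of the importance ratios (profile-likelihood method), smoothing by
# expected order statistics, truncation at the raw maximum.  Pareto k
# thresholds: <= 0.5 good, <= 0.7 ok, > 0.7 unreliable.

# generalized Pareto (GPD) shape/scale fit to exceedances x > 0
# (Zhang & Stephens 2009 profile method; xi is the tail-shape "Pareto k")
gpdfit <- function(x, regularize = TRUE) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 5) stop("need at least 5 exceedances to fit the GPD")
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[x > 0][1]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  xi_of_b <- function(bb) mean(log1p(-bb * x))
  xi_j <- vapply(b, xi_of_b, 1.0)
  ok <- is.finite(xi_j) & xi_j != 0 & (-b / xi_j) > 0
  b <- b[ok]; xi_j <- xi_j[ok]
  if (!length(b)) stop("GPD profile fit failed")
  L <- n * (log(-b / xi_j) - xi_j - 1)
  w <- 1 / vapply(seq_along(L), function(j) sum(exp(L - L[j])), 1.0)
  bhat <- sum(b * w)
  xi <- xi_of_b(bhat)
  sigma <- -xi / bhat
  if (regularize) xi <- (n * xi + 10 * 0.5) / (n + 10)
  list(k = xi, sigma = sigma)
}

# GPD quantile function in (k, sigma) parameterization
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns the smoothed
# log weights (unnormalized) and the fitted k
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (S < M + 5) stop("fewer draws than the PSIS tail size")
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  x <- exp(lw[tail_ids]) - exp(cutoff)
  if (sd(x) < 1e-12 || all(x <= 0)) {
    # degenerate (near-constant) tail: nothing to smooth
    return(list(lw = lw, k = -1))
  }
  fit <- gpdfit(x)
  p <- (seq_len(M) - 0.5) / M
  qq <- qgpd(p, fit$k, fit$sigma) + exp(cutoff)
  lw_new <- lw
  lw_new[tail_ids[order(lw[tail_ids])]] <- log(qq)
  lw_new <- pmin(lw_new, 0)   # truncate at the raw maximum
  list(lw = lw_new, k = fit$k)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO: approximate leave-one-out cross-validation
#'
#' @param pll Pointwise log-likelihood matrix (draws x observations), e.g.
#'   from [pointwise_loglik()], or a `phylou_fit` (uses its stored matrix).
#' @return Object of class `phylou_loo`: list with `elpd_loo`, `se_elpd`,
#'   `p_loo`, `pointwise` (per-observation elpd contributions), `pareto_k`
#'   (per observation; `k > 0.7` flagged unreliable) and `lppd`.
#' @export
psis_loo <- function(pll) {
  pll <- get_pll(pll)
  S <- nrow(pll); N <- ncol(pll)
  if (S < 100) stop("psis_loo needs at least 100 draws")
  elpd_i <- k_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-pll[, i])
    lw <- sm$lw - logsumexp(sm$lw)
    elpd_i[i] <- logsumexp(lw + pll[, i])
    k_i[i] <- sm$k
  }
  lppd_i <- apply(pll, 2, logsumexp) - log(S)
  out <- list(elpd_loo = sum(elpd_i),
              se_elpd = sqrt(N * var(elpd_i)),
              p_loo = sum(lppd_i - elpd_i),
              pointwise = setNames(elpd_i, colnames(pll)),
              pareto_k = setNames(k_i, colnames(pll)),
              lppd = sum(lppd_i),
              n_draws = S)
  class(out) <- "phylou_loo"
  if (any(k_i > 0.7))
    attr(out, "unreliable") <- names(which(k_i > 0.7))
  out
}

#' @export
print.phylou_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo %.2f (SE %.2f), p_loo %.2f\n",
              x$elpd_loo, x$se_elpd, x$p_loo))
  bad <- sum(x$pareto_k > 0.7)
  cat(sprintf("Pareto k: %d good (<=0.5), %d ok (<=0.7), %d unreliable (>0.7)\n",
              sum(x$pareto_k <= 0.5), sum(x$pareto_k > 0.5 & x$pareto_k <= 0.7),
              bad))
  if (bad) cat("  high-k observations:",
               paste(names(which(x$pareto_k > 0.7)), collapse = ", "), "\n")
  invisible(x)
}

#' Widely applicable information criterion
#'
#' `lppd - p_waic` on the elpd scale, with `p_waic` the summed pointwise
#' posterior variance of the log-likelihood.
#'
#' @inheritParams psis_loo
#' @return List with `elpd_waic`, `p_waic`, `se`, `pointwise`.
#' @export
waic <- function(pll) {
  pll <- get_pll(pll)
  S <- nrow(pll); N <- ncol(pll)
  lppd_i <- apply(pll, 2, logsumexp) - log(S)
  p_i <- apply(pll, 2, var)
  elpd_i <- lppd_i - p_i
  list(elpd_waic = sum(elpd_i), p_waic = sum(p_i),
       se = sqrt(N * var(elpd_i)),
       pointwise = setNames(elpd_i, colnames(pll)))
}

get_pll <- function(x) {
  if (inherits(x, "phylou_fit")) {
    if (is.null(x$pointwise)) x$pointwise <- pointwise_loglik(x)
    x <- x$pointwise
  }
  unclass(x)
}

#' Compare models by expected log pointwise predictive density
#'
#' Pairwise elpd differences with standard errors computed from the pointwise
#' contribution differences; a difference within +/- 2 SE is reported as no
#' substantial difference.
#'
#' @param ... Named `phylou_loo` objects (or a single list of them), all on
#'   the same observations.
#' @return Object of class `phylou_elpd_comparison`: list with `table`
#'   (models sorted by elpd) and `pairwise` (data.frame of differences).
#' @export
compare_elpd <- function(...) {
  loos <- list(...)
  if (length(loos) == 1 && !inherits(loos[[1]], "phylou_loo")) loos <- loos[[1]]
  if (is.null(names(loos)) || any(!nzchar(names(loos))))
    names(loos) <- paste0("model", seq_along(loos))
  Ns <- vapply(loos, function(l) length(l$pointwise), 1L)
  if (length(unique(Ns)) != 1)
    stop("models were evaluated on different numbers of observations")
  obs <- lapply(loos, function(l) names(l$pointwise))
  if (!all(vapply(obs, identical, TRUE, obs[[1]])))
    stop("models were evaluated on different observation sets")
  tab <- data.frame(model = names(loos),
                    elpd = vapply(loos, `[[`, 1.0, "elpd_loo"),
                    se = vapply(loos, `[[`, 1.0, "se_elpd"),
                    p_loo = vapply(loos, `[[`, 1.0, "p_loo"))
  tab <- tab[order(-tab$elpd), ]
  pairs <- t(utils::combn(names(loos), 2))
  pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    di <- loos[[a]]$pointwise - loos[[b]]$pointwise
    diff <- sum(di)
    se <- sqrt(length(di) * var(di))
    data.frame(model_a = a, model_b = b, elpd_diff = diff, se_diff = se,
               substantial = abs(diff) > 2 * se)
  }))
  structure(list(table = tab, pairwise = pw),
            class = "phylou_elpd_comparison")
}

#' @export
print.phylou_elpd_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("\npairwise differences (|diff| <= 2 SE => no substantial difference):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
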