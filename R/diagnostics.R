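# Convergence diagnostics: split rank-normalized potential scale reduction
# (R-hat) and effective sample size, with the standard flags (R-hat >= 1.1,
# n_eff < 100).

# rank-normalize a draws matrix (iterations x chains) jointly
rank_normalize <- function(x) {
  r <- rank(as.numeric(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

# split each chain in half -> iterations/2 x (2 chains) matrix
split_chains <- function(x) {
  S <- nrow(x)
  h <- floor(S / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(S - h + 1):S, , drop = FALSE])
}

# classic potential scale reduction on an iterations x chains matrix
rhat_basic <- function(x) {
  S <- nrow(x); M <- ncol(x)
  if (S < 2 || M < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- S * var(means)
  if (W <= 0) return(1)
  sqrt(((S - 1) / S * W + B / S) / W)
}

#' Split rank-normalized R-hat
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar R-hat (close to 1 at convergence; >= 1.1 signals trouble).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  rhat_basic(rank_normalize(split_chains(x)))
}

# combined-chain effective sample size (Geyer initial monotone sequence on
# rank-normalized split chains)
ess_mat <- function(x) {
  x <- split_chains(as.matrix(x))
  S <- nrow(x); M <- ncol(x)
  if (S < 3 || M < 1) return(NA_real_)
  if (all(apply(x, 2, var) == 0)) return(NA_real_)
  lag_max <- min(S - 1, 1000)
  acov <- matrix(0, lag_max + 1, M)
  for (m in seq_len(M)) {
    a <- acf(x[, m], lag.max = lag_max, type = "covariance", plot = FALSE,
             demean = TRUE)
    acov[, m] <- a$acf[, 1, 1]
  }
  chain_var <- acov[1, ] * S / (S - 1)
  W <- mean(chain_var)
  var_plus <- mean(acov[1, ]) * (S - 1) / S +
    (if (M > 1) var(colMeans(x)) else 0)
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - colMeans(t(acov[-1, , drop = FALSE]))) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 1
  t <- 1
  prev_pair <- Inf
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  max(S * M / tau, 1e-3)
}

#' Effective sample size (bulk)
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar ESS estimate.
#' @export
ess_bulk <- function(x) ess_mat(rank_normalize(as.matrix(x)))

#' Convergence diagnostics for a fit or draws array
#'
#' Computes split rank-normalized R-hat and bulk ESS per parameter and flags
#' parameters with `R-hat >= 1.1` or `n_eff < 100`.
#'
#' @param x A `phylou_fit` or a 3-d draws array (iterations x chains x
#'   parameters).
#' @return Data frame with `parameter`, `rhat`, `n_eff`, `flagged`.
#' @export
diagnostics <- function(x) {
  a <- if (inherits(x, "phylou_fit")) x$draws else x
  if (length(dim(a)) != 3) stop("draws must be iterations x chains x parameters")
  if (dim(a)[2] < 2)
    stop("diagnostics require at least 2 chains (split R-hat on a single ",
         "chain is a weak check)")
  if (dim(a)[1] < 4) stop("need at least 4 draws per chain")
  pn <- dimnames(a)[[3]]
  if (is.null(pn)) pn <- sprintf("par[%d]", seq_len(dim(a)[3]))
  rhat <- n_eff <- numeric(dim(a)[3])
  for (j in seq_len(dim(a)[3])) {
    m <- a[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, dim(a)[1], dim(a)[2])
    if (all(abs(m - m[1]) < 1e-300)) { rhat[j] <- 1; n_eff[j] <- NA; next }
    rhat[j] <- split_rhat(m)
    n_eff[j] <- ess_bulk(m)
  }
  data.frame(parameter = pn, rhat = rhat, n_eff = n_eff,
             flagged = !is.na(rhat) & (rhat >= 1.1 | (!is.na(n_eff) & n_eff < 100)))
}
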