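# R-facing interface to the built-in No-U-Turn sampler for arbitrary
# differentiable targets (the OU models use the compiled fast path through
# ou_fit()).

# overflow-safe per-chain RNG seed (kept inside 32-bit integer range)
chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1000 + chain) %% 2147483629)
}

#' Sample an arbitrary log density with the built-in NUTS sampler
#'
#' Adaptive Hamiltonian Monte Carlo (No-U-Turn criterion, dual-averaging step
#' size, diagonal mass-matrix adaptation).  Fixed seeds give bit-identical
#' draws on the same platform; divergent transitions are recorded.
#'
#' @param log_prob Function of the parameter vector returning the (possibly
#'   unnormalized) log density.
#' @param init Numeric initial parameter vector (one per chain if a list).
#' @param grad Gradient function; central finite differences when `NULL`.
#' @param chains,iter,warmup,seed,adapt_delta,max_treedepth Sampler settings.
#' @return List with `draws` (array: iterations x chains x parameters), `lp`,
#'   `divergent` (matrix), `treedepth`, `accept_stat`, `step_size`.
#' @export
nuts_sample <- function(log_prob, init, grad = NULL, chains = 2, iter = 4000,
                        warmup = floor(iter / 2), seed = 1, adapt_delta = 0.8,
                        max_treedepth = 10) {
  if (is.null(grad)) {
    grad <- function(q) {
      g <- numeric(length(q))
      for (j in seq_along(q)) {
        h <- 6e-6 * max(1, abs(q[j]))
        qp <- q; qp[j] <- q[j] + h
        qm <- q; qm[j] <- q[j] - h
        g[j] <- (log_prob(qp) - log_prob(qm)) / (2 * h)
      }
      g
    }
  }
  inits <- if (is.list(init)) init else rep(list(init), chains)
  if (length(inits) != chains) stop("need one init per chain")
  keep <- iter - warmup
  d <- length(inits[[1]])
  draws <- array(NA_real_, c(keep, chains, d))
  lp <- matrix(NA_real_, keep, chains)
  divergent <- matrix(0L, keep, chains)
  treedepth <- matrix(0L, keep, chains)
  accept <- matrix(NA_real_, keep, chains)
  step_size <- numeric(chains)
  for (ch in seq_len(chains)) {
    r <- nuts_sample_cpp(NULL, log_prob, grad, inits[[ch]], iter, warmup,
                         adapt_delta, max_treedepth, chain_seed(seed, ch))
    draws[, ch, ] <- r$draws
    lp[, ch] <- r$lp
    divergent[, ch] <- r$divergent
    treedepth[, ch] <- r$treedepth
    accept[, ch] <- r$accept_stat
    step_size[ch] <- r$step_size
  }
  list(draws = draws, lp = lp, divergent = divergent, treedepth = treedepth,
       accept_stat = accept, step_size = step_size)
}
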