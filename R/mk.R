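# Mk (continuous-time Markov chain) models for discrete characters:
# pruning-algorithm likelihood, ML rate estimation under ER / SYM / ARD rate
# structures, marginal ancestral-state reconstruction, and AIC — used to
# build regime paintings from observed tip states.

mk_n_params <- function(rate_model, m) {
  switch(rate_model,
         ER  = 1L,
         SYM = as.integer(m * (m - 1) / 2),
         ARD = as.integer(m * (m - 1)),
         stop("rate_model must be one of ER, SYM, ARD"))
}

# generator matrix from the off-diagonal rate parameters
mk_build_Q <- function(rates, rate_model, m) {
  Q <- matrix(0, m, m)
  if (rate_model == "ER") {
    Q[] <- rates[1]
  } else if (rate_model == "SYM") {
    k <- 1L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      Q[i, j] <- Q[j, i] <- rates[k]; k <- k + 1L
    }
  } else {
    k <- 1L
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) { Q[i, j] <- rates[k]; k <- k + 1L }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# postorder pruning; returns log-likelihood plus the per-node partial
# likelihood matrix L (scaled) for reuse in the marginal reconstruction
mk_prune <- function(tree, state_idx, Q, root_prior) {
  phy <- tree$phy
  n <- n_tips(tree); nn <- max(phy$edge); m <- nrow(Q)
  po <- ape::reorder.phylo(phy, "postorder")
  L <- matrix(1, nn, m)
  L[seq_len(n), ] <- 0
  L[cbind(seq_len(n), state_idx)] <- 1
  logscale <- 0
  Pedge <- vector("list", nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    P <- ape::matexpo(Q * po$edge.length[k])
    Pedge[[k]] <- P
    lc <- L[ch, ]
    sc <- max(lc)
    if (sc <= 0 || !is.finite(sc)) return(list(ll = -Inf))
    lc <- lc / sc
    logscale <- logscale + log(sc)
    L[ch, ] <- lc                       # store the scaled partials
    L[p, ] <- L[p, ] * as.vector(P %*% lc)
  }
  root <- root_node(tree)
  lik <- sum(root_prior * L[root, ])
  if (lik <= 0 || !is.finite(lik)) return(list(ll = -Inf))
  list(ll = log(lik) + logscale, L = L, po = po, Pedge = Pedge)
}

# marginal reconstruction: combine partial likelihoods below each node (L)
# with the likelihood of the rest of the tree (G, computed root-to-tip)
mk_marginals <- function(tree, prune, Q, root_prior) {
  phy <- tree$phy
  n <- n_tips(tree); nn <- max(phy$edge); m <- nrow(Q)
  L <- prune$L; po <- prune$po; Pedge <- prune$Pedge
  # per-parent list of (child, P %*% L_child)
  down <- vector("list", nn)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    down[[p]] <- c(down[[p]],
                   list(list(child = ch, msg = as.vector(Pedge[[k]] %*% L[ch, ]),
                             P = Pedge[[k]])))
  }
  G <- matrix(NA_real_, nn, m)
  root <- root_node(tree)
  G[root, ] <- root_prior
  for (k in rev(seq_len(nrow(po$edge)))) {   # preorder (parents first)
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    above <- G[p, ]
    for (sib in down[[p]]) if (sib$child != ch) above <- above * sib$msg
    P <- Pedge[[k]]
    g <- as.vector(crossprod(P, above))      # sum_sp above[sp] P[sp, sc]
    g[g < 0] <- 0
    sm <- sum(g)
    G[ch, ] <- if (sm > 0) g / sm else rep(1 / m, m)
  }
  marg <- G * L
  marg <- marg / rowSums(marg)
  marg
}

#' Mk ancestral-state reconstruction
#'
#' Maximizes the pruning-algorithm likelihood of an Mk model (uniform root
#' state distribution) over the off-diagonal generator rates, under one of
#' three rate structures: `ER` (one rate), `SYM` (symmetric) or `ARD` (all
#' rates different).  Marginal ancestral reconstructions combine the partial
#' likelihoods above and below each node.  Optimization is multi-start
#' box-constrained (`L-BFGS-B` on log rates, bounds `[1e-8, 100]` per unit
#' tree height) because the ARD likelihood surface is often multi-modal.
#'
#' @param tree A `phylou_tree`.
#' @param tip_states Named vector (by tip label) of discrete states.
#' @param rate_model One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param fixed_rates Optional vector of off-diagonal rates; skips
#'   optimization (used for oracle checks).
#' @param n_starts Number of seeded optimizer starts.
#' @param seed Seed controlling the start points.
#' @return An object of class `phylou_mk`: list with `rate_model`, `states`,
#'   `rates` (off-diagonal generator entries), `Q`, `log_likelihood`, `aic`,
#'   `node_marginals` (internal nodes x states, rows sum to 1), `ml_states`
#'   (argmax state per internal node; ties broken by lowest state index with
#'   a warning) and `tip_states`.
#' @export
mk_ancestral_states <- function(tree, tip_states, rate_model = c("ER", "SYM", "ARD"),
                                fixed_rates = NULL, n_starts = 3, seed = 1) {
  rate_model <- match.arg(rate_model)
  tree <- as_phylou_tree_keep_scale(tree)
  tip_states <- check_tip_states(tree, tip_states)
  states <- sort(unique(as.character(tip_states)))
  m <- length(states)
  if (m < 2)
    stop("only one observed state ('", states, "'): the painting is trivial; ",
         "assign the single regime to all nodes instead")
  state_idx <- match(as.character(tip_states), states)
  root_prior <- rep(1 / m, m)
  npar <- mk_n_params(rate_model, m)

  nll <- function(logr) {
    Q <- mk_build_Q(exp(logr), rate_model, m)
    -mk_prune(tree, state_idx, Q, root_prior)$ll
  }

  if (is.null(fixed_rates)) {
    stopifnot(n_starts >= 1)
    # heuristic base rate: one expected change over the tree
    base <- m / sum(tree$phy$edge.length)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    starts <- lapply(seq_len(n_starts), function(i) {
      mult <- c(1, 0.1, 10)[((i - 1) %% 3) + 1]
      log(base * mult) + rnorm(npar, 0, 0.25)
    })
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        optim(st, nll, method = "L-BFGS-B",
              lower = log(1e-8), upper = log(100)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best) || !is.finite(best$value))
      stop("Mk likelihood optimization failed (non-finite likelihood)")
    rates <- exp(best$par)
  } else {
    if (length(fixed_rates) != npar)
      stop("fixed_rates must have length ", npar, " for ", rate_model)
    rates <- fixed_rates
  }

  Q <- mk_build_Q(rates, rate_model, m)
  prune <- mk_prune(tree, state_idx, Q, root_prior)
  if (!is.finite(prune$ll)) stop("non-finite Mk likelihood at the fitted rates")
  marg <- mk_marginals(tree, prune, Q, root_prior)
  n <- n_tips(tree); nn <- max(tree$phy$edge)
  internal <- (n + 1L):nn
  node_marg <- marg[internal, , drop = FALSE]
  colnames(node_marg) <- states
  rownames(node_marg) <- node_labels(tree)[internal]

  ml_idx <- integer(nrow(node_marg))
  tie <- FALSE
  for (i in seq_len(nrow(node_marg))) {
    r <- node_marg[i, ]
    w <- which(abs(r - max(r)) < 1e-12)
    if (length(w) > 1) tie <- TRUE
    ml_idx[i] <- w[1]
  }
  if (tie) warning("ties in ML ancestral states broken by lowest state index")

  k_eff <- if (is.null(fixed_rates)) npar else 0L
  structure(list(
    rate_model = rate_model, states = states, rates = rates, Q = Q,
    log_likelihood = prune$ll,
    aic = 2 * k_eff - 2 * prune$ll,
    node_marginals = node_marg,
    ml_states = setNames(states[ml_idx], rownames(node_marg)),
    tip_states = setNames(as.character(tip_states), tip_labels(tree))),
    class = "phylou_mk")
}

#' @export
print.phylou_mk <- function(x, ...) {
  cat(sprintf("Mk %s model, %d states: logLik %.4f, AIC %.4f\n",
              x$rate_model, length(x$states), x$log_likelihood, x$aic))
  cat("rates:", signif(x$rates, 4), "\n")
  invisible(x)
}

#' Fit ER, SYM and ARD Mk models and compare by AIC
#'
#' @inheritParams mk_ancestral_states
#' @param rate_models Rate structures to fit.
#' @return List with `fits` (per rate model), `aic_table` (data.frame with
#'   `rate_model`, `k`, `log_likelihood`, `aic`) and `best` (name of the
#'   lowest-AIC model).
#' @export
mk_model_selection <- function(tree, tip_states,
                               rate_models = c("ER", "SYM", "ARD"),
                               n_starts = 3, seed = 1) {
  fits <- lapply(rate_models, function(rm)
    mk_ancestral_states(tree, tip_states, rm, n_starts = n_starts, seed = seed))
  names(fits) <- rate_models
  tab <- data.frame(
    rate_model = rate_models,
    k = vapply(fits, function(f) length(f$rates), 1L),
    log_likelihood = vapply(fits, function(f) f$log_likelihood, 1.0),
    aic = vapply(fits, function(f) f$aic, 1.0))
  best <- tab$rate_model[which.min(tab$aic)]
  list(fits = fits, aic_table = tab, best = best)
}

#' Regime painting from tip states via Mk reconstruction with AIC selection
#'
#' Convenience wrapper: fits the requested rate structures, selects the
#' lowest-AIC model, assigns internal nodes their ML states and returns the
#' painting together with the selection table.
#'
#' @inheritParams mk_model_selection
#' @return List with `painting`, `mk` (the selected fit) and `aic_table`.
#' @export
mk_painting <- function(tree, tip_states, rate_models = c("ER", "SYM", "ARD"),
                        n_starts = 3, seed = 1) {
  sel <- mk_model_selection(tree, tip_states, rate_models, n_starts, seed)
  mk <- sel$fits[[sel$best]]
  list(painting = painting_from_mk(tree, mk, tip_states),
       mk = mk, aic_table = sel$aic_table)
}
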