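# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written from first principles (path walks,
# exhaustive enumeration, dense linear algebra) and never call the code
# paths they check.

three_tip_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

two_regime_painting <- function(tree) {
  paint_regimes(tree, c(node_4 = "R0", node_5 = "R1"), c("R0", "R1"))
}

# independent shared-time oracle: explicit root-to-tip path walks
oracle_shared_times <- function(tree) {
  phy <- tree$phy
  n <- length(phy$tip.label)
  parent <- rep(NA_integer_, max(phy$edge))
  elen <- rep(NA_real_, max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- phy$edge.length
  path_of <- function(tip) {
    nodes <- integer(0); cur <- tip
    while (!is.na(cur)) { nodes <- c(cur, nodes); cur <- parent[cur] }
    nodes
  }
  times_of <- function(path) cumsum(c(0, elen[path[-1]]))
  paths <- lapply(seq_len(n), path_of)
  times <- lapply(paths, times_of)
  s <- matrix(0, n, n); d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pi <- paths[[i]]; pj <- paths[[j]]
    common <- max(which(pi[seq_len(min(length(pi), length(pj)))] ==
                          pj[seq_len(min(length(pi), length(pj)))]))
    s[i, j] <- times[[i]][common]
    d[i, j] <- (max(times[[i]]) - s[i, j]) + (max(times[[j]]) - s[i, j])
  }
  dimnames(s) <- dimnames(d) <- list(phy$tip.label, phy$tip.label)
  list(s = s, d = d)
}

# exhaustive-enumeration Mk likelihood and marginals (uniform root prior);
# transition probabilities from ape::matexpo, independent of the pruning code
oracle_mk <- function(tree, state_idx, Q) {
  phy <- tree$phy
  n <- length(phy$tip.label)
  nn <- max(phy$edge)
  m <- nrow(Q)
  internal <- (n + 1L):nn
  Pe <- lapply(seq_len(nrow(phy$edge)), function(k)
    ape::matexpo(Q * phy$edge.length[k]))
  combos <- as.matrix(expand.grid(rep(list(seq_len(m)), length(internal))))
  total <- 0
  node_post <- matrix(0, length(internal), m)
  for (r in seq_len(nrow(combos))) {
    assign_state <- integer(nn)
    assign_state[seq_len(n)] <- state_idx
    assign_state[internal] <- combos[r, ]
    pr <- 1 / m                      # uniform root prior
    for (k in seq_len(nrow(phy$edge))) {
      pe <- Pe[[k]]
      pr <- pr * pe[assign_state[phy$edge[k, 1]], assign_state[phy$edge[k, 2]]]
    }
    total <- total + pr
    for (ii in seq_along(internal))
      node_post[ii, combos[r, ii]] <- node_post[ii, combos[r, ii]] + pr
  }
  list(loglik = log(total), marginals = node_post / total)
}

# simulate tip states under an Mk model (preorder transitions)
simulate_mk_states <- function(tree, Q, seed) {
  set.seed(seed)
  phy <- ape::reorder.phylo(tree$phy, "cladewise")
  m <- nrow(Q)
  nn <- max(phy$edge)
  st <- integer(nn)
  root <- length(phy$tip.label) + 1L
  st[root] <- sample.int(m, 1)
  for (k in seq_len(nrow(phy$edge))) {
    P <- ape::matexpo(Q * phy$edge.length[k])
    st[phy$edge[k, 2]] <- sample.int(m, 1, prob = P[st[phy$edge[k, 1]], ])
  }
  setNames(letters[st[seq_len(length(phy$tip.label))]], phy$tip.label)
}

# dense multivariate-normal log density (oracle for likelihood assembly)
oracle_dmvnorm <- function(y, mu, V) {
  n <- length(y)
  ch <- chol(V)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
}

# a small shared fit used by several test files (built once per run)
.shared <- new.env()
shared_small_fit <- function() {
  if (!is.null(.shared$fit)) return(.shared$fit)
  tree <- simulate_tree(20, seed = 401)
  painting <- random_clade_painting(tree, K = 2, size_range = c(5, 14),
                                    seed = 402)
  spec <- ou_model_spec("multi_optima_direct")
  params <- list(t_half = 0.2, v = 0.05, theta = c(0, 1), beta = 0.4,
                 sigma2_x = 1)
  X <- simulate_bm(tree, 1, seed = 403)
  Xc <- X - mean(X)
  y <- simulate_response(tree, painting, spec, params, X = Xc, seed = 404)
  traits <- data.frame(species = tip_labels(tree), y = unname(y),
                       x = unname(X))
  .shared$truth <- params
  .shared$fit <- ou_fit(tree, traits, "y", "x", painting = painting,
                        spec = spec, chains = 2, iter = 700, warmup = 350,
                        seed = 405, quiet = TRUE)
  .shared$fit
}
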