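# Generative engine: seeded birth-death trees, Brownian-motion predictors,
# responses drawn from the same mean/covariance assembly the likelihood
# uses, measurement error, and the standard 100-tip / 4-regime validation
# fixture.  Every operation is a pure function of (inputs, seed); child
# seeds are derived from the master seed by a fixed counter scheme so adding
# a new random step never perturbs earlier streams.

#' Derive a child seed from a master seed
#'
#' `derive_seed(seed, k) = (seed + 1000003 k) mod 2147483629`, kept in
#' `[1, 2^31)` so all derived seeds are valid R integer seeds.
#'
#' @param seed Master seed (integer).
#' @param k Counter (integer >= 0).
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483629
  as.integer(max(s, 1))
}

#' Simulate an ultrametric birth-death tree scaled to unit height
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates (default Yule).
#' @param seed Integer seed (required; reproducible).
#' @return A unit-height `phylou_tree`.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth <= 0 || death < 0) stop("need birth > 0 and death >= 0")
  phy <- NULL
  for (try in seq_len(50)) {
    set.seed(derive_seed(seed, try - 1))
    phy <- tryCatch(ape::rphylo(n_tips, birth = birth, death = death,
                                fossils = FALSE),
                    error = function(e) NULL)
    if (!is.null(phy)) break
  }
  if (is.null(phy))
    stop("birth-death simulation failed to produce ", n_tips,
         " extant tips after 50 attempts")
  scale_to_unit_height(as_phylou_tree(phy))
}

#' Simulate Brownian motion along a tree
#'
#' Recursive normal increments along branches from a root value of `x0`.
#'
#' @param tree A `phylou_tree`.
#' @param sigma2 Instantaneous variance of the BM process (>= 0).
#' @param seed Integer seed.
#' @param x0 Root value.
#' @return Named tip values (tip order).
#' @export
simulate_bm <- function(tree, sigma2 = 1, seed, x0 = 0) {
  if (missing(seed)) stop("an explicit seed is required")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  tree <- as_phylou_tree_keep_scale(tree)
  phy <- ape::reorder.phylo(tree$phy, "cladewise")
  nn <- max(phy$edge)
  vals <- rep(NA_real_, nn)
  vals[root_node(tree)] <- x0
  set.seed(seed)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    vals[ch] <- vals[p] + rnorm(1, 0, sqrt(sigma2 * phy$edge.length[k]))
  }
  setNames(vals[seq_len(n_tips(tree))], tip_labels(tree))
}

#' Simulate a response from the generative OU model
#'
#' Draws `Y` from the multivariate normal with mean [model_mean()] and
#' covariance [model_covariance()] at the true parameters (for the adaptive
#' model, conditional on the supplied predictor values).
#'
#' @param tree A `phylou_tree`.
#' @param painting A `phylou_painting`.
#' @param spec A `phylou_spec` (its `kind`/`slopes` select the generative
#'   model).
#' @param params True parameters: `t_half`, `v`, `theta`, and `beta`,
#'   `sigma2_x` where applicable.
#' @param X Predictor values (centered as desired; the mean uses them as
#'   given).
#' @param seed Integer seed.
#' @param n Number of replicate datasets (mean and covariance are assembled
#'   once).
#' @return Named response vector `Y_true` (no measurement error), or an
#'   `n` x N matrix when `n > 1`.
#' @export
simulate_response <- function(tree, painting, spec, params, X = NULL, seed,
                              n = 1) {
  if (missing(seed)) stop("an explicit seed is required")
  tree <- as_phylou_tree_keep_scale(tree)
  mu <- model_mean(tree, painting, spec, params, X)
  if (params$v == 0) {
    V <- model_covariance(tree, painting, spec,
                          within_v(params, 1e-12), se_y = NULL)
  } else {
    V <- model_covariance(tree, painting, spec, params, se_y = NULL)
  }
  set.seed(seed)
  N <- length(mu)
  Z <- matrix(rnorm(N * n), N, n)
  if (max(abs(V)) < 1e-24) {
    out <- matrix(mu, n, N, byrow = TRUE, dimnames = list(NULL, names(mu)))
  } else {
    L <- t(chol(V))
    out <- t(mu + L %*% Z)
    colnames(out) <- names(mu)
  }
  if (n == 1) return(setNames(out[1, ], names(mu)))
  out
}

within_v <- function(params, v) { params$v <- v; params }

#' Add Gaussian measurement error
#'
#' @param values Named numeric vector of true values.
#' @param sd Measurement-error standard deviation (>= 0), recycled.
#' @param seed Integer seed.
#' @return List with `observed` and `reported_se` (the same `sd`, per
#'   species, as it would be supplied to a fit).
#' @export
add_measurement_error <- function(values, sd, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (any(sd < 0)) stop("sd must be >= 0")
  sd <- rep(sd, length.out = length(values))
  set.seed(seed)
  noise <- rnorm(length(values), 0, sd)
  list(observed = values + noise,
       reported_se = setNames(sd, names(values)))
}

#' Random clade-structured K-regime painting
#'
#' The root regime plus `K - 1` regimes painted on internal nodes chosen
#' uniformly among those subtending between `size_range[1]` and
#' `size_range[2]` tips; paintings are re-drawn (new derived seed) until
#' every regime holds at least `min_tips` tips.
#'
#' @param tree A `phylou_tree`.
#' @param K Number of regimes.
#' @param size_range Allowed clade sizes for the painted nodes.
#' @param min_tips Minimum tips per regime.
#' @param seed Integer seed.
#' @return A `phylou_painting` with regimes `R1` (root) ... `RK`.
#' @export
random_clade_painting <- function(tree, K = 4, size_range = c(5, 40),
                                  min_tips = 5, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  tree <- as_phylou_tree_keep_scale(tree)
  n <- n_tips(tree); nn <- max(tree$phy$edge)
  clade_size <- integer(nn)
  po <- ape::reorder.phylo(tree$phy, "postorder")
  clade_size[seq_len(n)] <- 1L
  for (k in seq_len(nrow(po$edge)))
    clade_size[po$edge[k, 1]] <- clade_size[po$edge[k, 1]] +
      clade_size[po$edge[k, 2]]
  root <- root_node(tree)
  cand <- setdiff(which(clade_size >= size_range[1] &
                          clade_size <= size_range[2]), c(seq_len(n), root))
  if (length(cand) < K - 1)
    stop("not enough candidate clades of the requested size")
  labs <- node_labels(tree)
  regime_names <- paste0("R", seq_len(K))
  for (try in seq_len(200)) {
    set.seed(derive_seed(seed, try - 1))
    nodes <- sample(cand, K - 1)
    asg <- c(setNames("R1", labs[root]),
             setNames(regime_names[-1], labs[nodes]))
    painting <- paint_regimes(tree, asg, regime_names)
    counts <- table(factor(tip_regimes(tree, painting),
                           levels = seq_len(K)))
    if (all(counts >= min_tips)) return(painting)
  }
  stop("could not find a painting with >= ", min_tips, " tips per regime")
}

#' The standard simulation-study fixture
#'
#' Generates the validation design: an `n_tips` unit-height birth-death
#' tree (a seeded stand-in for the subsampled empirical primate phylogeny,
#' which cannot be redistributed in code), four regimes painted on random
#' clades, a BM predictor with `sigma2_x = 1`, a multi-optima adaptive
#' varying-effects response with `t_half = 0.1`, `v = 0.01`,
#' `theta = (1, 2, 3, 4)`, `beta = (0.75, 0.5, 0.35, 0.25)`, and N(0, 0.01^2)
#' measurement error added to both variables (with 0.01 reported as the
#' estimated SE).  The predictor is mean-centered before entering the
#' response mean, so the recorded optima are "optima at the average
#' predictor value", matching the fit-side convention.
#'
#' @param seed Master seed (required).
#' @param n_tips Tree size (default 100).
#' @param t_half,v,theta,beta,sigma2_x,me_sd True parameter values.
#' @param K Number of regimes (default `length(theta)`).
#' @param min_tips Minimum tips per regime in the painting.
#' @return Object of class `phylou_sim`: list with `tree`, `painting`,
#'   `spec`, `X` (raw BM values), `X_obs`, `Y_true`, `Y_obs`, `se_x`, `se_y`,
#'   `traits` (a fit-ready data.frame), and `truth` (all parameters + seeds).
#' @export
ou_sim_study <- function(seed, n_tips = 100, t_half = 0.1, v = 0.01,
                         theta = c(1, 2, 3, 4),
                         beta = c(0.75, 0.5, 0.35, 0.25),
                         sigma2_x = 1, me_sd = 0.01, K = length(theta),
                         min_tips = 5) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(length(beta) %in% c(1L, K))
  tree <- simulate_tree(n_tips, birth = 1, death = 0, seed = derive_seed(seed, 1))
  painting <- random_clade_painting(
    tree, K = K, min_tips = min_tips,
    size_range = c(min_tips, max(2 * min_tips, floor(n_tips / 2.5))),
    seed = derive_seed(seed, 2))
  X <- simulate_bm(tree, sigma2 = sigma2_x, seed = derive_seed(seed, 3))
  Xc <- X - mean(X)
  spec <- ou_model_spec("multi_optima_adaptive", multilevel = "none",
                        slopes = if (length(beta) == K) "by_regime" else "shared")
  params <- list(t_half = t_half, v = v, theta = theta, beta = beta,
                 sigma2_x = sigma2_x)
  Y <- simulate_response(tree, painting, spec, params, X = Xc,
                         seed = derive_seed(seed, 4))
  mey <- add_measurement_error(Y, me_sd, seed = derive_seed(seed, 5))
  mex <- add_measurement_error(X, me_sd, seed = derive_seed(seed, 6))
  traits <- data.frame(species = tip_labels(tree),
                       y = unname(mey$observed),
                       y_se = unname(mey$reported_se),
                       x = unname(mex$observed),
                       x_se = unname(mex$reported_se),
                       regime = painting$regime_names[tip_regimes(tree, painting)],
                       stringsAsFactors = FALSE)
  structure(list(
    tree = tree, painting = painting, spec = spec,
    X = X, X_obs = mex$observed, Y_true = Y, Y_obs = mey$observed,
    se_x = mex$reported_se, se_y = mey$reported_se, traits = traits,
    truth = list(t_half = t_half, v = v, theta = theta, beta = beta,
                 sigma2_x = sigma2_x, me_sd = me_sd, n_tips = n_tips,
                 seed = seed,
                 regime_tip_counts = as.integer(table(factor(
                   tip_regimes(tree, painting), levels = seq_len(K)))))),
    class = "phylou_sim")
}

#' @export
print.phylou_sim <- function(x, ...) {
  cat(sprintf("phylou_sim: %d tips, %d regimes (tips per regime: %s)\n",
              n_tips(x$tree), length(x$painting$regime_names),
              paste(x$truth$regime_tip_counts, collapse = "/")))
  cat(sprintf("  truth: t_half %.3g, v %.3g, theta (%s), beta (%s)\n",
              x$truth$t_half, x$truth$v,
              paste(x$truth$theta, collapse = ", "),
              paste(x$truth$beta, collapse = ", ")))
  invisible(x)
}

#' Write a simulation result as the file set the CLI consumes
#'
#' Writes `tree.nwk` (Newick), `regimes.csv` (node_label, regime),
#' `traits.csv` (species, y, y_se, x, x_se, regime) and `truth.json`.
#'
#' @param sim A `phylou_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phy <- sim$tree$phy
  n <- n_tips(sim$tree)
  phy$node.label <- node_labels(sim$tree)[(n + 1):max(phy$edge)]
  paths <- c(tree = file.path(dir, "tree.nwk"),
             regimes = file.path(dir, "regimes.csv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "truth.json"))
  ape::write.tree(phy, paths["tree"])
  write_regime_assignments(sim$tree, sim$painting, paths["regimes"])
  write.csv(sim$traits, paths["traits"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
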