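# Deterministic OU core: reparameterizations, Hansen regime-weight design
# matrices, OU residual covariances, the phylogenetic correction factor rho,
# and model mean/covariance assembly.  The matrix kernels are implemented
# once in C++ and shared with the sampler; these wrappers expose them with
# tip labels attached.

#' Convert between phylogenetic half-life and rate of adaptation
#'
#' `t_half = ln(2) / alpha`: the expected time for the trait to close half
#' the gap between the ancestral state and the primary optimum.
#'
#' @param t_half Half-life (> 0), in units of tree height.
#' @return The rate of adaptation `alpha` (or the half-life, for the
#'   inverse).
#' @export
half_life_to_alpha <- function(t_half) {
  if (any(t_half <= 0)) stop("t_half must be > 0")
  log(2) / t_half
}

#' @rdname half_life_to_alpha
#' @param alpha Rate of adaptation (> 0).
#' @export
alpha_to_half_life <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  log(2) / alpha
}

#' Convert between the OU diffusion variance and the stationary variance
#'
#' `v = sigma2_y / (2 alpha)`: the equilibrium among-species variance of an
#' OU process evolving around a stationary optimum.
#'
#' @param sigma2_y Instantaneous variance of the OU white-noise term (> 0).
#' @param alpha Rate of adaptation (> 0).
#' @return The stationary variance `v` (or `sigma2_y`, for the inverse).
#' @export
stationary_variance <- function(sigma2_y, alpha) {
  if (any(sigma2_y <= 0) || any(alpha <= 0)) stop("arguments must be > 0")
  sigma2_y / (2 * alpha)
}

#' @rdname stationary_variance
#' @param v Stationary variance (> 0).
#' @export
sigma2_y_from_stationary <- function(v, alpha) {
  if (any(v <= 0) || any(alpha <= 0)) stop("arguments must be > 0")
  2 * alpha * v
}

#' Phylogenetic correction factor rho
#'
#' `rho(x) = 1 - (1 - exp(-x)) / x` with `rho(0) = 0` by continuity.  The
#' evolutionary regression slope is the optimal slope times `rho(alpha T)`;
#' `rho -> 1` as adaptation becomes instantaneous and `rho -> 0` in the
#' Brownian-motion limit.
#'
#' @param alpha Rate of adaptation (> 0).
#' @param t Elapsed time (>= 0), typically the tip depth.
#' @return `rho(alpha * t)`, in `[0, 1)`.
#' @export
rho_correction <- function(alpha, t) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  x <- alpha * t
  vapply(x, cpp_rho_factor, 1.0)
}

# flatten a painting's tip lineages into the C++ segment encoding (0-based)
painting_segments <- function(tree, painting) {
  lin <- painting$tip_lineages
  nseg <- vapply(lin, nrow, 1L)
  list(seg_tip = rep(seq_along(lin), nseg) - 1L,
       seg_reg = unlist(lapply(lin, function(x) x$regime), use.names = FALSE) - 1L,
       seg_ta = unlist(lapply(lin, function(x) x$t_start), use.names = FALSE),
       seg_tb = unlist(lapply(lin, function(x) x$t_end), use.names = FALSE),
       root_reg = painting$node_regime[root_node(tree)] - 1L)
}

#' Hansen regime-weight design matrix
#'
#' Row `i` gives, for each regime, the exponentially discounted fraction of
#' tip `i`'s history spent in that regime: a lineage segment `(k, ta, tb)`
#' contributes `exp(-alpha (T_i - tb)) - exp(-alpha (T_i - ta))` to regime
#' `k`, and the residual root mass `exp(-alpha T_i)` is assigned to the
#' root's regime, so each row sums to 1.
#'
#' @param alpha Rate of adaptation (> 0).
#' @param tree A `phylou_tree`.
#' @param painting A `phylou_painting` for the tree.
#' @return N x K matrix with tip labels as row names and regime names as
#'   column names.
#' @export
regime_weights <- function(alpha, tree, painting) {
  if (alpha <= 0) stop("alpha must be > 0")
  tree <- as_phylou_tree_keep_scale(tree)
  seg <- painting_segments(tree, painting)
  W <- cpp_regime_weights(alpha, n_tips(tree), length(painting$regime_names),
                          seg$seg_tip, seg$seg_reg, seg$seg_ta, seg$seg_tb,
                          unname(tip_depths(tree)), seg$root_reg)
  dimnames(W) <- list(tip_labels(tree), painting$regime_names)
  W
}

#' OU residual covariance matrix
#'
#' `V[i, j] = v exp(-alpha d_ij) (1 - exp(-2 alpha s_ij))` where `s` is the
#' shared-ancestry time and `d` the patristic distance between tips.
#'
#' @param alpha Rate of adaptation (> 0).
#' @param v Stationary variance (> 0).
#' @param shared A [shared_times()] result (or a `phylou_tree`).
#' @return Symmetric positive-definite N x N matrix, tip-label order.
#' @export
ou_covariance <- function(alpha, v, shared) {
  if (alpha <= 0 || v <= 0) stop("alpha and v must be > 0")
  if (inherits(shared, "phylou_tree")) shared <- shared_times(shared)
  V <- cpp_ou_covariance(alpha, v, shared$s, shared$d)
  dimnames(V) <- dimnames(shared$s)
  V
}
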