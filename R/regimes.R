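# Regime paintings: assignment of every node (root included) to one of K
# selective regimes, and the per-tip decomposition of each root-to-tip
# lineage into (regime, t_start, t_end) segments.
#
# Convention (documented, and assumed throughout): a regime assigned to a
# node takes effect on the branches BELOW that node, i.e. the branch from a
# parent to a child carries the PARENT's regime, and the root's regime
# applies from time 0.  A regime change painted on an internal node therefore
# splits the lineages through it at that node's time.  A tip's own regime
# label names the tip but does not color any branch.

#' Paint selective regimes onto a tree
#'
#' Assignments are given for a subset of nodes (the root must be resolvable);
#' all other nodes inherit the regime of their nearest painted ancestor.
#'
#' @param tree A `phylou_tree`.
#' @param assignments Named character vector `node -> regime`.  Names may be
#'   tip labels, internal node labels (see `node_labels`), or ape node ids
#'   given as integers/characters.
#' @param regime_names Optional ordered character vector of regime names
#'   (defaults to the sorted unique assigned regimes).
#' @return An object of class `phylou_painting`: list with `regime_names`,
#'   `node_regime` (integer regime index per node, ape numbering), and
#'   `tip_lineages` (per tip, a data.frame with columns `regime`, `t_start`,
#'   `t_end` tiling `[0, tip depth]`).
#' @export
paint_regimes <- function(tree, assignments, regime_names = NULL) {
  tree <- as_phylou_tree_keep_scale(tree)
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("'assignments' must be a named vector (node -> regime)")
  assignments <- setNames(as.character(assignments), trimws(names(assignments)))
  if (is.null(regime_names)) regime_names <- sort(unique(unname(assignments)))
  unknown <- setdiff(unique(unname(assignments)), regime_names)
  if (length(unknown))
    stop("regime name(s) not in 'regime_names': ", paste(unknown, collapse = ", "))

  phy <- tree$phy
  nn <- max(phy$edge)
  labs <- node_labels(tree)
  idx <- match(names(assignments), labs)
  as_id <- suppressWarnings(as.integer(names(assignments)))
  idx[is.na(idx) & !is.na(as_id) & as_id >= 1 & as_id <= nn] <-
    as_id[is.na(idx) & !is.na(as_id) & as_id >= 1 & as_id <= nn]
  if (anyNA(idx))
    stop("unknown node(s) in assignments: ",
         paste(names(assignments)[is.na(idx)], collapse = ", "))

  assigned <- rep(NA_integer_, nn)
  assigned[idx] <- match(unname(assignments), regime_names)
  root <- root_node(tree)
  if (is.na(assigned[root]))
    stop("the root must be assigned a regime (unpainted root)")

  # inherit in preorder
  node_regime <- assigned
  ord <- preorder_nodes(tree)
  parent <- parent_pointers(tree)
  for (nd in ord) {
    if (nd == root) next
    if (is.na(node_regime[nd])) node_regime[nd] <- node_regime[parent[nd]]
  }

  painting <- structure(
    list(regime_names = regime_names, node_regime = node_regime,
         tip_lineages = NULL),
    class = "phylou_painting")
  painting$tip_lineages <- compute_tip_lineages(tree, painting)
  painting
}

# preorder traversal (root first)
preorder_nodes <- function(tree) {
  e <- ape::reorder.phylo(tree$phy, "cladewise")$edge
  c(root_node(tree), e[, 2])
}

# walk each root->tip path, splitting at regime changes; branch regime is the
# regime of its PARENT node (change takes effect below the painted node)
compute_tip_lineages <- function(tree, painting) {
  n <- n_tips(tree)
  times <- tree$node_times
  reg <- painting$node_regime
  parent <- parent_pointers(tree)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    path <- integer(0)
    cur <- i
    while (!is.na(cur)) { path <- c(cur, path); cur <- parent[cur] }
    # path: root ... tip
    segs_r <- integer(0); segs_a <- numeric(0); segs_b <- numeric(0)
    for (j in seq_len(length(path) - 1L)) {
      p <- path[j]; ch <- path[j + 1L]
      r <- reg[p]                       # branch carries parent's regime
      t0 <- times[p]; t1 <- times[ch]
      if (t1 <= t0) next                # zero-length branch
      if (length(segs_r) && segs_r[length(segs_r)] == r) {
        segs_b[length(segs_b)] <- t1    # merge contiguous same-regime
      } else {
        segs_r <- c(segs_r, r); segs_a <- c(segs_a, t0); segs_b <- c(segs_b, t1)
      }
    }
    if (!length(segs_r)) {              # tip at the root's time (degenerate)
      segs_r <- reg[root_node(tree)]; segs_a <- 0; segs_b <- 0
    }
    out[[i]] <- data.frame(regime = segs_r, t_start = segs_a, t_end = segs_b)
  }
  names(out) <- tip_labels(tree)
  out
}

#' @export
print.phylou_painting <- function(x, ...) {
  tab <- table(factor(x$regime_names[x$node_regime], levels = x$regime_names))
  cat("phylou_painting:", length(x$regime_names), "regimes\n")
  print(tab)
  invisible(x)
}

#' Tip regime indices of a painting
#' @param tree A `phylou_tree`.
#' @param painting A `phylou_painting` for that tree.
#' @return Integer vector (tip order) of each tip's own regime index.
#' @export
tip_regimes <- function(tree, painting) {
  painting$node_regime[seq_len(n_tips(tree))]
}

#' Regime painting from an Mk ancestral-state reconstruction
#'
#' Internal nodes take their maximum-likelihood state, tips their observed
#' state; the regime set is the observed state set.
#'
#' @param tree A `phylou_tree`.
#' @param mk_result An [mk_ancestral_states()] result for the same tree.
#' @param tip_states Named vector of observed tip states.
#' @return A `phylou_painting`.
#' @export
painting_from_mk <- function(tree, mk_result, tip_states) {
  tree <- as_phylou_tree_keep_scale(tree)
  tip_states <- check_tip_states(tree, tip_states)
  states <- mk_result$states
  labs <- node_labels(tree)
  n <- n_tips(tree)
  nn <- max(tree$phy$edge)
  asg <- c(setNames(as.character(tip_states), tip_labels(tree)),
           setNames(mk_result$ml_states, labs[(n + 1L):nn]))
  paint_regimes(tree, asg, regime_names = states)
}

#' Read a regime-assignment file
#'
#' Delimited text with columns `node_label` and `regime`.
#'
#' @param file Path to the file.
#' @return Named character vector suitable for [paint_regimes()].
#' @export
read_regime_assignments <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("node_label", "regime")
  if (!all(need %in% names(df)))
    stop("regime file must have columns: ", paste(need, collapse = ", "))
  setNames(as.character(df$regime), trimws(as.character(df$node_label)))
}

#' Write a painting as a regime-assignment file
#' @param tree A `phylou_tree`.
#' @param painting A `phylou_painting`.
#' @param file Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_regime_assignments <- function(tree, painting, file) {
  labs <- node_labels(tree)
  df <- data.frame(node_label = labs,
                   regime = painting$regime_names[painting$node_regime],
                   stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}

# validate and order tip states to the tree's tip order
check_tip_states <- function(tree, tip_states) {
  if (is.null(names(tip_states)))
    stop("'tip_states' must be named by tip label")
  names(tip_states) <- trimws(names(tip_states))
  missing <- setdiff(tip_labels(tree), names(tip_states))
  if (length(missing))
    stop("tips without a state: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(tip_states), tip_labels(tree))
  if (length(extra))
    stop("states for unknown tips: ", paste(extra, collapse = ", "))
  tip_states[tip_labels(tree)]
}
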