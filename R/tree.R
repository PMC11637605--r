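# Tree ingestion and time bookkeeping.  A phylou_tree wraps an ape "phylo"
# object together with node times measured forward from the root (root = 0)
# and the scale factor recorded by unit-height rescaling.

#' Parse a Newick string or file into a time-calibrated tree
#'
#' Reads a rooted tree with branch lengths (time units) and computes node
#' times measured forward from the root.  Polytomies are allowed; zero-length
#' internal branches are collapsed into polytomies with a warning; zero-length
#' terminal branches are accepted.
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file Path to a Newick file.
#' @return An object of class `phylou_tree`: a list with elements `phy`
#'   (the `ape::phylo` tree), `node_times` (time from root for every node,
#'   tips first, in `ape` node numbering), `height` (maximum tip time),
#'   and `scale_factor` (original height / current height; 1 on ingestion).
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  # cheap structural pre-check so malformed input reports a position
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "malformed Newick: %d unclosed '(' at end of string (position %d)",
      depth, nchar(text)))
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick: ape could not parse the string")
  as_phylou_tree(phy)
}

#' Build a phylou_tree from an ape phylo object
#'
#' @param phy An `ape::phylo` tree, rooted, with branch lengths.
#' @return A `phylou_tree`; see [parse_newick()].
#' @export
as_phylou_tree <- function(phy) {
  if (inherits(phy, "phylou_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("tree must have a branch length on every edge")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  phy$tip.label <- trimws(phy$tip.label)
  if (any(!nzchar(phy$tip.label))) stop("tip labels must be non-empty")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  ntip <- length(phy$tip.label)
  internal <- phy$edge[, 2] > ntip
  if (any(internal & phy$edge.length == 0)) {
    warning("zero-length internal branches collapsed into polytomies")
    phy <- ape::di2multi(phy, tol = 1e-12)
  }
  node_times <- ape::node.depth.edgelength(phy)
  height <- max(node_times[seq_len(ntip)])
  if (height <= 0) stop("tree height must be positive")
  structure(list(phy = phy, node_times = node_times, height = height,
                 scale_factor = 1), class = "phylou_tree")
}

#' @export
print.phylou_tree <- function(x, ...) {
  cat(sprintf("phylou_tree: %d tips, height %.6g, scale_factor %.6g, %s\n",
              n_tips(x), x$height, x$scale_factor,
              if (is_ultrametric(x)) "ultrametric" else "non-ultrametric"))
  invisible(x)
}

#' Number of tips of a phylou_tree
#' @param tree A `phylou_tree`.
#' @return Integer tip count.
#' @export
n_tips <- function(tree) length(tree$phy$tip.label)

#' Tip labels of a phylou_tree (defines all matrix orderings)
#' @param tree A `phylou_tree`.
#' @return Character vector of tip labels in the tree's stored order; every
#'   matrix or vector returned by the package follows this order.
#' @export
tip_labels <- function(tree) tree$phy$tip.label

#' Tip depths (time from root to each tip)
#' @param tree A `phylou_tree`.
#' @return Named numeric vector, tip-label order.
#' @export
tip_depths <- function(tree) {
  n <- n_tips(tree)
  setNames(tree$node_times[seq_len(n)], tip_labels(tree))
}

#' Is the tree ultrametric (common tip depth)?
#' @param tree A `phylou_tree`.
#' @param tol Relative tolerance on the spread of tip depths.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}

#' Rescale a tree to unit height
#'
#' Divides all branch lengths by the current height and records the original
#' height in `scale_factor` so that quantities estimated on the unit-height
#' scale (e.g. the phylogenetic half-life) can be back-transformed to the
#' original time units.  Idempotent: rescaling an already unit-height tree
#' leaves it unchanged while accumulating the scale factor.
#'
#' @param tree A `phylou_tree`.
#' @return A `phylou_tree` with `height == 1` and updated `scale_factor`.
#' @export
scale_to_unit_height <- function(tree) {
  tree <- as_phylou_tree_keep_scale(tree)
  h <- tree$height
  if (!is.finite(h) || h <= 0) stop("tree height must be positive to rescale")
  tree$phy$edge.length <- tree$phy$edge.length / h
  tree$node_times <- tree$node_times / h
  tree$scale_factor <- tree$scale_factor * h
  tree$height <- 1
  tree
}

# as_phylou_tree() resets scale_factor; internal variant preserving it
as_phylou_tree_keep_scale <- function(tree) {
  if (inherits(tree, "phylou_tree")) return(tree)
  as_phylou_tree(tree)
}

#' Shared ancestry times and patristic distances between tips
#'
#' For tips `i`, `j`: `s[i, j]` is the time (from the root) of their most
#' recent common ancestor, and `d[i, j]` the patristic time-distance between
#' them, so that `d[i, j] = depth_i + depth_j - 2 s[i, j]`.
#'
#' @param tree A `phylou_tree`.
#' @return List with matrices `s` and `d` (tip-label order) and the vector
#'   `depths` of tip depths.
#' @export
shared_times <- function(tree) {
  tree <- as_phylou_tree_keep_scale(tree)
  s <- ape::vcv.phylo(tree$phy)               # shared time from the root
  s <- s[tip_labels(tree), tip_labels(tree)]  # enforce stored tip order
  depths <- tip_depths(tree)
  d <- outer(depths, depths, "+") - 2 * s
  d[d < 0 & d > -1e-12] <- 0
  list(s = s, d = d, depths = depths)
}

# root node id in ape numbering
root_node <- function(tree) n_tips(tree) + 1L

# parent pointer vector: parent[node] = parent id, NA for root
parent_pointers <- function(tree) {
  phy <- tree$phy
  nn <- max(phy$edge)
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent
}

# path of node ids from root to a given node (inclusive)
root_path <- function(tree, node) {
  parent <- parent_pointers(tree)
  path <- integer(0)
  cur <- node
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- parent[cur]
  }
  path
}

# stable textual labels for all nodes: tips keep their labels, internal nodes
# use existing labels when present else "node_<id>"
node_labels <- function(tree) {
  phy <- tree$phy
  n <- n_tips(tree)
  nn <- max(phy$edge)
  labs <- character(nn)
  labs[seq_len(n)] <- phy$tip.label
  int <- (n + 1L):nn
  if (!is.null(phy$node.label) && length(phy$node.label) == nn - n) {
    nl <- trimws(phy$node.label)
    empty <- !nzchar(nl) | is.na(nl)
    nl[empty] <- paste0("node_", int[empty])
    labs[int] <- nl
  } else {
    labs[int] <- paste0("node_", int)
  }
  labs
}
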