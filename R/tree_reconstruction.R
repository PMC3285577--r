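#' Neighbor-joining tree from an ML distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}) on the division
#' distance matrix. Input labels are expected in canonical (sorted) order as
#' produced by [build_distance_matrix()], which makes the agglomeration
#' deterministic.
#'
#' @param dm an `ms_dist` object, or a symmetric numeric matrix with
#'   dimnames.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "ms_dist")) dm$d else dm
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  ape::nj(d)
}

#' Root a tree at the median pseudo-cell
#'
#' The root signature competes in neighbor joining as an ordinary taxon
#' (leaf `"root_median"`). This function re-roots the tree at the internal
#' node to which that pseudo-leaf attaches, removes the pseudo-leaf and its
#' pendant edge, and returns the rooted lineage tree; depths are measured
#' from the new root, which sits at depth 0 by construction.
#'
#' @param tree unrooted `phylo` containing leaf `root_median`.
#' @return rooted `phylo` of class `c("lineage_tree", "phylo")`.
#' @export
root_at_median <- function(tree) {
  tip <- match("root_median", tree$tip.label)
  if (is.na(tip)) stop("tree has no 'root_median' leaf")
  attach_node <- tree$edge[tree$edge[, 2L] == tip, 1L]
  rooted <- ape::root(tree, node = attach_node, resolve.root = FALSE)
  rooted <- ape::drop.tip(rooted, "root_median")
  class(rooted) <- c("lineage_tree", "phylo")
  rooted
}

#' Depth of every leaf
#'
#' Depth is the branch-length sum from the root to each terminal leaf, in
#' divisions. Neighbor joining can produce small negative branch lengths;
#' since depths are division counts these are clamped to zero before summing
#' (default), while the tree object itself keeps the raw reconstruction.
#'
#' @param tree rooted `phylo` / `lineage_tree`.
#' @param clamp_negative clamp negative branch lengths to 0 first (default).
#' @return named numeric vector, cell_id -> depth.
#' @export
leaf_depths <- function(tree, clamp_negative = TRUE) {
  if (!ape::is.rooted(tree)) stop("leaf_depths needs a rooted tree")
  if (clamp_negative) tree$edge.length <- pmax(tree$edge.length, 0)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  setNames(depths, tree$tip.label)
}

#' Write a rooted lineage tree as Newick
#'
#' Branch lengths are written in fixed 6-decimal format, so a read-back
#' round trip preserves topology exactly and lengths to 1e-6.
#'
#' @param tree rooted `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (!ape::is.rooted(tree)) stop("write_newick expects a rooted lineage tree")
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  class(tree) <- c("lineage_tree", "phylo")
  tree
}

#' Full reconstruction pipeline for one mouse
#'
#' Root signature (per-allele median), ML distance matrix including the root
#' pseudo-cell, neighbor joining, median rooting, and depth readout.
#'
#' @param cells list of `cell_signature` from a single mouse (>= 3).
#' @param model a [stepwise_model()].
#' @param clamp_negative passed to [leaf_depths()].
#' @return list with `tree` (rooted `lineage_tree`), `depths` (named vector),
#'   `root` (`root_signature`), and `dm` (`ms_dist`).
#' @export
reconstruct_tree <- function(cells, model = stepwise_model(),
                             clamp_negative = TRUE) {
  root <- compute_root_signature(cells)
  dm <- build_distance_matrix(cells, root, model)
  tree <- root_at_median(neighbor_joining(dm))
  list(tree = tree, depths = leaf_depths(tree, clamp_negative),
       root = root, dm = dm)
}
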