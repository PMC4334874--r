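# Distance-based tree inference, outgroup rooting, monophyly testing and
# pseudo-bootstrap branch support. Tree handling stands on 'ape' (phylo
# objects, Newick I/O); the GBDP-specific part is the support convention:
# replicate distance matrices come from HSP resampling, each replicate is
# re-built with the same inference settings, and support is the percentage
# of replicates containing the same bipartition.

#' Build a distance tree
#'
#' Neighbor joining by default; \code{method = "bme"} uses balanced minimum
#' evolution with nearest-neighbor-interchange improvement
#' (\code{ape::fastme.bal}). Negative branch lengths are clamped to zero.
#' Deterministic under fixed input order.
#'
#' @param m Labeled symmetric distance matrix (or \code{gbdp_matrix}) over
#'   at least 3 labels.
#' @param method \code{"nj"} or \code{"bme"}.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
build_tree <- function(m, method = c("nj", "bme")) {
  if (inherits(m, "gbdp_matrix")) m <- m$distances
  m <- dist_matrix(m)
  if (nrow(m) < 3) stopf("tree inference needs at least 3 labels")
  method <- match.arg(method)
  tree <- switch(method,
                 nj = ape::nj(stats::as.dist(m)),
                 bme = ape::fastme.bal(stats::as.dist(m), nni = TRUE,
                                       spr = FALSE, tbr = FALSE))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# tip-label sets of all internal edges' clades, for the current rooting
clade_sets <- function(tree) {
  parts <- ape::prop.part(tree)
  lapply(parts, function(idx) unname(sort(attr(parts, "labels")[idx])))
}

#' Root a tree with an outgroup
#'
#' The outgroup must form a clade (one side of some bipartition) of the
#' unrooted tree; the root is placed on the branch separating outgroup from
#' ingroup.
#'
#' @param tree An \code{ape::phylo} tree.
#' @param outgroup_labels Tip labels of the outgroup (a proper non-empty
#'   subset of the leaves).
#' @return A rooted \code{ape::phylo} tree.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  tips <- tree$tip.label
  missing <- setdiff(outgroup_labels, tips)
  if (length(missing) > 0) stopf("unknown outgroup label: %s", missing[1])
  if (length(outgroup_labels) == 0 ||
      length(outgroup_labels) >= length(tips))
    stopf("outgroup must be a proper non-empty subset of the leaves")
  og <- sort(unique(outgroup_labels))
  if (length(og) > 1) {
    sets <- clade_sets(ape::unroot(tree))
    ingroup <- sort(setdiff(tips, og))
    ok <- any(vapply(sets, function(s)
      identical(s, og) || identical(s, ingroup), logical(1)))
    if (!ok) stopf("outgroup not monophyletic in the unrooted tree")
  }
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

#' Is a label set monophyletic in a rooted tree?
#'
#' TRUE iff some node's leaf descendants equal the set exactly (single
#' tips are trivially monophyletic).
#'
#' @param tree A rooted \code{ape::phylo} tree.
#' @param labels Subset of the tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  missing <- setdiff(labels, tips)
  if (length(missing) > 0) stopf("unknown label: %s", missing[1])
  labels <- sort(unique(labels))
  if (length(labels) == 1) return(TRUE)
  any(vapply(clade_sets(tree), function(s) identical(s, labels),
             logical(1)))
}

#' Annotate branch support from pseudo-bootstrap replicate matrices
#'
#' Builds one tree per replicate matrix (same inference method as the point
#' tree) and sets, for each internal branch of the point tree, the
#' percentage of replicate trees containing the same bipartition. All
#' values are kept in the data layer (\code{$node.label} and attribute
#' \code{"support"}); hiding values <= 50 is a rendering decision (see
#' \code{\link{write_tree_newick}}).
#'
#' @param tree Point-estimate \code{ape::phylo} tree.
#' @param replicate_matrices List of labeled distance matrices over the
#'   same label set (from \code{\link{gbdp_bootstrap}}).
#' @param method Tree-building method applied to each replicate.
#' @return The tree with \code{$node.label} set to support percentages.
#' @export
annotate_support <- function(tree, replicate_matrices,
                             method = c("nj", "bme")) {
  method <- match.arg(method)
  if (length(replicate_matrices) == 0) stopf("no replicate matrices")
  for (m in replicate_matrices)
    if (!setequal(rownames(m), tree$tip.label))
      stopf("replicate matrix labels do not match the tree")
  reps <- lapply(replicate_matrices, build_tree, method = method)
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps), 1)
  tree$node.label <- as.character(support)
  attr(tree, "support") <- support
  tree
}

#' Write a tree to Newick
#'
#' @param tree An \code{ape::phylo} tree, optionally with support values in
#'   \code{$node.label}.
#' @param path Output path.
#' @param hide_support_below If non-NULL, support values less than or equal
#'   to this (percent) are blanked in the rendered file -- the customary
#'   "show if larger than 50\%" display rule -- without touching the data
#'   layer.
#' @export
write_tree_newick <- function(tree, path, hide_support_below = NULL) {
  if (!is.null(hide_support_below) && !is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(sup) & sup <= hide_support_below] <- ""
  }
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#' @param path Input path.
#' @return An \code{ape::phylo} tree.
#' @export
read_tree_newick <- function(path) ape::read.tree(path)
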