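#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] with validation: tip labels must be
#' unique and every edge must carry a non-negative branch length. Unlabeled
#' internal nodes are accepted.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree))
    stop("malformed Newick file: ", path)
  validate_tree(tree)
  tree
}

#' Write a tree to Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Check that tree tips and alignment ids coincide
#'
#' Tips present in the tree but absent from the alignment (or vice versa) are
#' a hard error: silently dropping either side would misalign weights and
#' sequences and corrupt the downstream Potts fit.
#'
#' @param tree an [ape::phylo] tree.
#' @param aln an [msa] object.
#' @return invisibly `TRUE` when the label sets match.
#' @export
check_tree_alignment <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "msa"))
  only_tree <- setdiff(tree$tip.label, aln$ids)
  only_aln <- setdiff(aln$ids, tree$tip.label)
  if (length(only_tree) || length(only_aln))
    stop("tree/alignment mismatch; tips missing from alignment: [",
         paste(only_tree, collapse = ", "), "], ids missing from tree: [",
         paste(only_aln, collapse = ", "), "]")
  invisible(TRUE)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path so the two
#' maximally distant tips become equidistant from the root. If the tree has no
#' branch-length signal at all (all branches zero), rooting is arbitrary and a
#' warning is issued.
#'
#' @param tree an [ape::phylo] tree, rooted or unrooted.
#' @return a rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L)
    stop("midpoint rooting needs at least 2 tips")
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0) {
    warning("all branch lengths are zero; rooting at an arbitrary tip")
    return(ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

# children of `node` in the edge table, with the connecting edge indices
.children <- function(tree, node) {
  e <- which(tree$edge[, 1L] == node)
  list(nodes = tree$edge[e, 2L], edges = e)
}

#' ACL current-flow tree weights
#'
#' The Altschul-Carroll-Lipman scheme models the rooted tree as a resistor
#' network: a unit current enters at the root, every branch is a resistor with
#' resistance equal to its length, and every tip is grounded. The weight of a
#' tip is the current flowing out of it, so closely related tips (which share
#' most of their path to the root) split their current and are jointly
#' down-weighted. Weights are relative and sum to 1.
#'
#' Computed by the recursive parallel-resistance reduction: the effective
#' resistance of a subtree is its root branch plus the parallel combination of
#' its children, and current entering a node splits among children inversely
#' to their effective resistances. Zero-length branches would short the
#' network and are replaced by an epsilon resistance of `1e-8` times the mean
#' branch length.
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return a raw [weight_vector] (method `acl`) over the tips, summing to 1.
#' @export
acl_weights <- function(tree) {
  validate_tree(tree)
  # the basal node is taken as the root; a star tree is rooted at its center
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  bl <- tree$edge.length
  mbl <- mean(bl)
  if (mbl == 0) mbl <- 1
  bl[bl <= 0] <- 1e-8 * mbl
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  # branch resistance above each node (edge leading to it); root has none
  r_above <- rep(NA_real_, nnode)
  r_above[tree$edge[, 2L]] <- bl
  # postorder: effective resistance of each subtree seen from above its branch
  post <- rev(.preorder_nodes(tree))
  r_eff <- rep(NA_real_, nnode)
  for (u in post) {
    if (u <= ntip) {
      r_eff[u] <- r_above[u]
    } else {
      ch <- .children(tree, u)$nodes
      r_par <- 1 / sum(1 / r_eff[ch])
      r_eff[u] <- (if (u == root) 0 else r_above[u]) + r_par
    }
  }
  # preorder: split current among children inversely to effective resistance
  current <- rep(0, nnode)
  current[root] <- 1
  for (u in .preorder_nodes(tree)) {
    if (u <= ntip) next
    ch <- .children(tree, u)$nodes
    g <- 1 / r_eff[ch]
    current[ch] <- current[u] * g / sum(g)
  }
  weight_vector(current[seq_len(ntip)], "acl", ids = tree$tip.label)
}

# nodes in preorder (root first, every parent before its children)
.preorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, u)
    kids <- tree$edge[tree$edge[, 1L] == u, 2L]
    stack <- c(stack, rev(kids))
  }
  ord
}

#' GSC branch-partition tree weights
#'
#' The Gerstein-Sonnhammer-Chothia scheme partitions every branch length of a
#' rooted tree among the tips below it. Tips start with their pendant branch
#' lengths; moving rootward, the branch above each internal node is divided
#' among its descendant tips in proportion to their accumulated weights (an
#' equal split when all are still zero). Each tip's final weight is therefore
#' a weighted sum of the branch lengths on its root path, in branch-length
#' units, and the weights sum to the tree's total branch length. Long isolated
#' branches earn large weights; tips in dense clades share theirs.
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return a raw [weight_vector] (method `gsc`) over the tips.
#' @export
gsc_weights <- function(tree) {
  validate_tree(tree)
  # the basal node is taken as the root; see midpoint_root() for rooting
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  bl_above <- rep(0, ntip + tree$Nnode)
  bl_above[tree$edge[, 2L]] <- tree$edge.length
  w <- rep(0, ntip)
  w[seq_len(ntip)] <- bl_above[seq_len(ntip)]
  # descendant tip sets, filled bottom-up
  tipsets <- vector("list", ntip + tree$Nnode)
  for (u in rev(.preorder_nodes(tree))) {
    if (u <= ntip) {
      tipsets[[u]] <- u
      next
    }
    kids <- tree$edge[tree$edge[, 1L] == u, 2L]
    tips <- unlist(tipsets[kids])
    tipsets[[u]] <- tips
    if (u == root) next
    tot <- sum(w[tips])
    share <- if (tot > 0) w[tips] / tot else rep(1 / length(tips), length(tips))
    w[tips] <- w[tips] + bl_above[u] * share
  }
  weight_vector(w, "gsc", ids = tree$tip.label)
}

#' RelTime-style rescaling to a relative time scale
#'
#' Converts a rooted branch-length tree (substitutions/site) into an
#' ultrametric tree in relative time, preserving topology. At each internal
#' node the relative height is estimated bottom-up as the tip-count-weighted
#' mean of the child lineages' (branch + height); the implied relative rate of
#' a child lineage is its observed depth divided by the node's consensus
#' height, and rescaling the branches to the consensus heights equalizes all
#' root-to-tip paths. At the root the two (or more) immediate lineages are
#' averaged the same way, i.e. their rates are not separately identifiable and
#' are treated symmetrically. No rate-significance testing is performed. A
#' monotonicity guard clamps a node's height at the maximum child height, so a
#' lineage observed as deeper than its parent's consensus yields a zero-length
#' branch rather than a negative one. Multifurcations are averaged over all
#' children directly (equivalent to resolving them with zero-length branches).
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return an ultrametric [ape::phylo] tree with identical topology, branch
#'   lengths in relative time (root height preserved from the mean input
#'   depth, so an already-ultrametric tree is a fixed point).
#' @export
reltime_rescale <- function(tree) {
  validate_tree(tree)
  if (!ape::is.rooted(tree))
    stop("reltime_rescale requires a rooted tree; run midpoint_root() first")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  bl_above <- rep(0, nnode)
  bl_above[tree$edge[, 2L]] <- tree$edge.length
  h <- rep(0, nnode)       # relative height above the tips
  ntips_below <- rep(1L, nnode)
  for (u in rev(.preorder_nodes(tree))) {
    if (u <= ntip) next
    kids <- tree$edge[tree$edge[, 1L] == u, 2L]
    ntips_below[u] <- sum(ntips_below[kids])
    depth_k <- bl_above[kids] + h[kids]
    h[u] <- sum(ntips_below[kids] * depth_k) / ntips_below[u]
    h[u] <- max(h[u], max(h[kids]))  # monotonicity guard
  }
  out <- tree
  out$edge.length <- h[tree$edge[, 1L]] - h[tree$edge[, 2L]]
  out
}
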