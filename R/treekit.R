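# Distance-based trees and quantification of the phylogenetic backbone: a
# tree has a backbone when a single connected path of branches carries a
# large fraction of the total internal branch length. backboneScore()
# reports that fraction; classification into "backboned" or not is left to
# the user because the notion is inherently graded.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via \pkg{ape}) with negative branch-length
#' estimates clamped to zero. Used here for tree-shape diagnostics on
#' binary simulated data, where substitution-model inference adds nothing.
#'
#' @param dist symmetric, zero-diagonal distance matrix (or `dist`
#'   object) over at least 3 strains.
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("neighbour joining needs at least 3 strains")
  tree <- ape::nj(as.dist(dist))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Backbone score of a tree
#'
#' The maximum, over simple paths through the tree, of the summed internal
#' branch lengths on the path, divided by the total internal branch length.
#' Internal branches are those with no tip endpoint; terminal branches may
#' lie on the path but contribute no length, and the tree is treated as
#' unrooted. A perfect star scores 0 (by convention, also when there is no
#' internal length at all); a caterpillar, whose internal branches all lie
#' on one path, scores 1. The score is invariant to tip relabelling and to
#' uniform rescaling of branch lengths.
#'
#' @param tree a `phylo` object with at least 3 tips.
#' @return the backbone fraction in `[0, 1]`.
#' @export
backboneScore <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 3) stop("backbone score needs at least 3 tips")
  edge <- tree$edge
  len <- tree$edge.length
  if (is.null(len)) stop("tree has no branch lengths")
  internal <- edge[, 1] > ntip & edge[, 2] > ntip
  total <- sum(len[internal])
  if (total <= 0) return(0)
  w <- ifelse(internal, len, 0)     # terminal branches carry no weight
  nn <- max(edge)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, w[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[k]))
  }
  # iterative post-order DFS from the (arbitrary) root node ntip + 1:
  # down[v] = best weighted path descending from v; the best path overall
  # combines the two best child descents through some vertex
  root <- ntip + 1L
  parent <- integer(nn)
  order <- integer(0)
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    nbr <- adj[[v]]
    for (r in seq_len(NROW(nbr))) {
      u <- nbr[r, 1]
      if (u != parent[v]) {
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  down <- numeric(nn)
  best <- 0
  for (v in rev(order)) {
    nbr <- adj[[v]]
    tops <- c(0, 0)                 # two best descents among children
    for (r in seq_len(NROW(nbr))) {
      u <- nbr[r, 1]
      if (u == parent[v]) next
      cand <- down[u] + nbr[r, 2]
      if (cand > tops[1]) { tops[2] <- tops[1]; tops[1] <- cand }
      else if (cand > tops[2]) tops[2] <- cand
    }
    down[v] <- tops[1]
    best <- max(best, tops[1] + tops[2])
  }
  best / total
}
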