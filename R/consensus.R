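#' Non-trivial bipartitions of a tree
#'
#' Decomposes an unrooted tree into the splits induced by its internal
#' edges. Each split is canonicalized as the sorted leaf set of the side
#' not containing the reference taxon (the lexicographically smallest
#' leaf), encoded as a single "|"-joined string. Trivial splits (either
#' side smaller than 2 leaves) are excluded, so trees with fewer than 4
#' leaves yield the empty set.
#'
#' @param tree a \code{phylo} object.
#' @return character vector of canonical split keys.
#' @export
bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4) return(character(0))
  ref <- sort(labs)[1]
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  n_nodes <- max(tree$edge)
  below <- vector("list", n_nodes)
  for (i in seq_len(n)) below[[i]] <- labs[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  root <- n + 1L
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next                      # leaf edge: trivial split
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Majority-rule consensus of gene trees
#'
#' Counts every non-trivial bipartition across the input trees and retains
#' those present in strictly more than \code{threshold} of them (strict
#' majority: a split in exactly half the trees is excluded). For
#' \code{threshold >= 0.5} the retained splits are pairwise compatible and
#' assemble into a unique tree; unresolved parts remain polytomies. Each
#' internal edge carries its support as the percentage of input trees
#' containing the split. With \code{extended = TRUE}, minority splits are
#' greedily added in decreasing support order when compatible with the
#' accepted set.
#'
#' @param trees list of \code{phylo} objects over one identical leaf set.
#' @param threshold retention threshold as a fraction of trees (default
#'   strict majority, 0.5).
#' @param extended greedily add compatible minority splits.
#' @return object of class \code{consensus_tree}: \code{tree} (a
#'   \code{phylo} whose node labels are integer-percent supports),
#'   \code{splits} (data.frame \code{split, count, support}), \code{n_trees}.
#' @export
majority_consensus <- function(trees, threshold = 0.5, extended = FALSE) {
  if (length(trees) == 0) stop("need at least one input tree")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(leafsets)) {
    if (!identical(leafsets[[i]], leafsets[[1]])) {
      stop("tree ", i, " has a different leaf set from tree 1")
    }
  }
  labs <- leafsets[[1]]
  n_trees <- length(trees)
  all_keys <- unlist(lapply(trees, bipartitions), use.names = FALSE)
  counts <- sort(table(all_keys), decreasing = TRUE)
  support <- 100 * as.numeric(counts) / n_trees
  retained <- as.numeric(counts) / n_trees > threshold
  keep_keys <- names(counts)[retained]
  if (extended) {
    for (k in names(counts)[!retained]) {
      cand <- strsplit(k, "|", fixed = TRUE)[[1]]
      ok <- all(vapply(keep_keys, function(kk) {
        a <- strsplit(kk, "|", fixed = TRUE)[[1]]
        compatible_clades(a, cand)
      }, logical(1)))
      if (ok) keep_keys <- c(keep_keys, k)
    }
  }
  clades <- lapply(keep_keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  sup_of <- stats::setNames(support, names(counts))
  tree <- assemble_from_clades(labs, clades,
                               round(unname(sup_of[keep_keys])))
  structure(list(
    tree = tree,
    splits = data.frame(split = names(counts),
                        count = as.integer(counts),
                        support = support,
                        retained = names(counts) %in% keep_keys,
                        stringsAsFactors = FALSE),
    n_trees = n_trees, threshold = threshold
  ), class = "consensus_tree")
}

# Two clades on the same leaf universe (both excluding the reference taxon)
# are compatible iff disjoint or nested.
compatible_clades <- function(a, b) {
  inter <- length(intersect(a, b))
  inter == 0 || inter == length(a) || inter == length(b)
}

# Build a phylo from a laminar family of clades (none containing the
# reference leaf): nest clades by containment under a root holding every
# leaf, then emit Newick with support node labels.
assemble_from_clades <- function(labs, clades, supports) {
  ord <- order(lengths(clades))
  clades <- clades[ord]
  supports <- supports[ord]
  n_cl <- length(clades)
  # parent[i]: index of the smallest clade strictly containing clade i
  # (0 = root). Clades are sorted by size, so scan larger clades only.
  parent_cl <- integer(n_cl)
  for (i in seq_len(n_cl)) {
    parent_cl[i] <- 0L
    for (j in seq_len(n_cl)) {
      if (lengths(clades)[j] > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]])) {
        parent_cl[i] <- j
        break
      }
    }
  }
  # Leaf attachment: smallest clade containing the leaf, else root.
  leaf_parent <- vapply(labs, function(l) {
    for (j in seq_len(n_cl)) if (l %in% clades[[j]]) return(j)
    0L
  }, integer(1))
  render <- function(node) {
    kids_cl <- which(parent_cl == node)
    kids_leaf <- labs[leaf_parent == node]
    parts <- c(kids_leaf, vapply(kids_cl, render, character(1)))
    body <- paste(parts, collapse = ",")
    if (node == 0L) {
      paste0("(", body, ");")
    } else {
      paste0("(", body, ")", supports[node])
    }
  }
  ape::read.tree(text = render(0L))
}

#' Test whether two trees share the same unrooted topology
#'
#' @param t1,t2 \code{phylo} objects over the same leaf set.
#' @return TRUE iff the Robinson-Foulds distance is zero.
#' @export
same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
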