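## Species-tree helpers. Trees are rooted `ape::phylo` objects; a *branch*
## is identified by the clade below it, as the sorted "+"-joined leaf set
## (stable across ape's internal node renumbering). The branch above the
## root (id = all leaves) is a valid branch: a character dated there predates
## the sampled species.

#' Leaves below every node of a rooted tree
#'
#' @param tree a rooted `phylo` object.
#' @return a list indexed by node number (tips first, then internal nodes),
#'   each element the character vector of tip labels in that node's clade.
#' @keywords internal
node_leafsets <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  ## edges in ape are not guaranteed post-order; iterate children before
  ## parents by sorting internal nodes on decreasing number of descendants
  ## via repeated passes (trees here are small).
  done <- c(rep(TRUE, n_tip), rep(FALSE, tree$Nnode))
  while (!all(done)) {
    for (nd in which(!done)) {
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      if (all(done[kids])) {
        sets[[nd]] <- sort(unique(unlist(sets[kids])))
        done[nd] <- TRUE
      }
    }
  }
  sets
}

#' Branch identifier from a leaf set
#' @param leaves character vector of tip labels.
#' @return a single string, the sorted leaf set joined by `"+"`.
#' @export
branch_id <- function(leaves) paste(sort(unique(leaves)), collapse = "+")

#' All branch ids of a rooted tree
#'
#' One branch per node (terminal branches for tips, internal branches for
#' internal nodes, and the branch above the root, whose id is the full leaf
#' set).
#'
#' @param tree a rooted `phylo` object.
#' @return character vector of branch ids.
#' @export
tree_branches <- function(tree) {
  vapply(node_leafsets(tree), branch_id, character(1))
}

#' Leaves below a branch id
#' @param id a branch id produced by [branch_id()].
#' @return character vector of tip labels.
#' @export
branch_leaves <- function(id) strsplit(id, "+", fixed = TRUE)[[1]]

## MRCA as a leafset: smallest clade containing all `leaves`.
mrca_leafset <- function(tree, leaves) {
  sets <- node_leafsets(tree)
  sizes <- lengths(sets)
  ok <- vapply(sets, function(s) all(leaves %in% s), logical(1))
  sets[ok][[which.min(sizes[ok])]]
}

#' Read a rooted species tree from a Newick file
#' @param path file path.
#' @return a `phylo` object.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (!ape::is.rooted(tr)) stop("species tree must be rooted")
  tr
}
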