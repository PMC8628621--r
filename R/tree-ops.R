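#' Prune a tree to a set of tips
#'
#' Removes all tips not in `keep` and suppresses every resulting
#' single-child (unifurcating) internal node, summing the branch lengths of
#' merged edges.  When the chain of suppressed nodes reaches the root, the
#' accumulated length above the new root is stored as `root.edge`, so the
#' root-to-tip path length of every retained tip (see [tip_depth()]) is
#' conserved exactly.  Relative tip order is preserved.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (>= 2, all present
#'   in the tree).
#' @return A `"phylo"` object whose tip set equals `keep`.
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' write_newick(prune_tree(tr, c("A", "C")))  # "(A:4,C:4);"
#' @export
prune_tree <- function(tree, keep) {
  if (!inherits(tree, "phylo")) stop_validation("'tree' must be a 'phylo' object")
  keep <- as.character(keep)
  if (anyDuplicated(keep)) keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L) {
    stop_validation("unknown tip label(s): ",
                    paste(sQuote(unknown), collapse = ", "))
  }
  if (length(keep) < 2L) {
    stop_validation("cannot reduce tree below 2 tips")
  }
  if (length(keep) == length(tree$tip.label)) return(tree)

  root_extra <- 0
  has_bl <- !is.null(tree$edge.length)
  if (has_bl) {
    # depth of the kept tips' MRCA = total length of the root chain that
    # keep.tip will suppress
    mrca <- ape::getMRCA(tree, keep)
    depths <- ape::node.depth.edgelength(tree)
    root_extra <- depths[mrca]
    if (!is.null(tree$root.edge)) root_extra <- root_extra + tree$root.edge
  }
  pruned <- ape::keep.tip(tree, keep)
  pruned$root.edge <- NULL
  if (has_bl && root_extra > 0) pruned$root.edge <- root_extra
  pruned
}

#' Root-to-tip path length
#'
#' Sums branch lengths from a tip to the root, including `root.edge` when
#' present (so depths are comparable before and after [prune_tree()]).
#'
#' @param tree A `"phylo"` object with branch lengths on the path.
#' @param tip A single tip label.
#' @return A numeric scalar.
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' tip_depth(tr, "A")  # 4
#' @export
tip_depth <- function(tree, tip) {
  if (!inherits(tree, "phylo")) stop_validation("'tree' must be a 'phylo' object")
  if (length(tip) != 1L) stop_validation("'tip' must be a single label")
  idx <- match(as.character(tip), tree$tip.label)
  if (is.na(idx)) stop_validation("unknown tip label: ", sQuote(tip))
  if (is.null(tree$edge.length)) {
    stop_validation("tree has no branch lengths")
  }
  total <- 0
  node <- idx
  root <- length(tree$tip.label) + 1L
  edge <- tree$edge
  while (node != root) {
    row <- which(edge[, 2L] == node)
    if (length(row) != 1L) stop_validation("malformed tree: node without a single parent")
    len <- tree$edge.length[row]
    if (is.na(len)) {
      stop_validation("missing branch length on the path from ", sQuote(tip),
                      " to the root")
    }
    total <- total + len
    node <- edge[row, 1L]
  }
  if (!is.null(tree$root.edge)) total <- total + tree$root.edge
  total
}

#' Simulate a random phylogenetic tree
#'
#' Random topology by recursive uniform bipartition of the tip set with
#' branch lengths drawn i.i.d. uniform on (0, 1) and tip labels
#' `t1..t<n>` (the `rtree` scheme from \pkg{ape}).  A given `seed` always
#' yields the same tree; the caller's RNG state is restored afterwards.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed; `NULL` uses (and advances) the current
#'   RNG stream.
#' @return A `"phylo"` object with `n_tips` tips.
#' @examples
#' identical(write_newick(simulate_tree(10, seed = 1)),
#'           write_newick(simulate_tree(10, seed = 1)))
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2) {
    stop_validation("'n_tips' must be a single integer >= 2")
  }
  with_seed(seed, ape::rtree(as.integer(n_tips)))
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
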