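# Brute-force pruning oracle, independent of prune_tree(): deletes tips one
# at a time from an adjacency representation, suppressing single-child nodes
# after each deletion (summing merged branch lengths; lengths of suppressed
# root-chain edges accumulate in root_extra).  Renders Newick for comparison.
oracle_prune <- function(tree, keep) {
  stopifnot(!is.null(tree$edge.length))
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  len <- rep(NA_real_, n_all)
  len[tree$edge[, 2]] <- tree$edge.length
  children <- vector("list", n_all)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]
    children[[p]] <- c(children[[p]], tree$edge[r, 2])
  }
  root <- n_tip + 1L
  root_extra <- if (!is.null(tree$root.edge)) tree$root.edge else 0
  alive <- rep(TRUE, n_all)

  for (t in which(!(tree$tip.label %in% keep))) {
    p <- parent[t]
    alive[t] <- FALSE
    children[[p]] <- setdiff(children[[p]], t)
    v <- p
    while (!is.na(v) && alive[v]) {
      kids <- children[[v]]
      if (length(kids) != 1L) break
      k <- kids[1L]
      pv <- parent[v]
      if (is.na(pv)) {
        # root unifurcation: child becomes root, its edge joins root_extra
        root_extra <- root_extra + len[k]
        len[k] <- NA_real_
        parent[k] <- NA_integer_
        alive[v] <- FALSE
        root <- k
        v <- k
      } else {
        # splice v out of the chain pv -> v -> k
        len[k] <- len[k] + len[v]
        parent[k] <- pv
        children[[pv]][children[[pv]] == v] <- k
        alive[v] <- FALSE
        v <- pv
      }
    }
  }

  render <- function(v) {
    lab <- if (v <= n_tip) tree$tip.label[v] else ""
    suffix <- if (is.na(len[v])) "" else sprintf(":%.17g", len[v])
    if (v <= n_tip) return(paste0(lab, suffix))
    kids <- children[[v]]
    paste0("(", paste(vapply(kids, render, character(1)), collapse = ","),
           ")", suffix)
  }
  root_part <- if (root_extra > 0) sprintf(":%.17g", root_extra) else ""
  list(
    newick = paste0(render(root), root_part, ";"),
    root_extra = root_extra
  )
}

# Trees drawn with >=1 polytomy opportunity come straight from
# simulate_tree; this wraps a reproducible draw of a random keep-set.
random_keep <- function(tree, min_keep = 2L) {
  n <- length(tree$tip.label)
  size <- sample(seq.int(min_keep, n), 1L)
  sample(tree$tip.label, size)
}

# Assert the coupling invariant on a phylotable object.
expect_coupled <- function(td) {
  labs <- as.character(td$dat[[td$label]])
  trees <- if (inherits(td$phy, "phylo")) list(td$phy) else unclass(td$phy)
  for (tr in trees) {
    expect_setequal(labs, tr$tip.label)
  }
  expect_identical(labs, trees[[1]]$tip.label)
  expect_equal(nrow(td$dat), length(trees[[1]]$tip.label))
}

# Non-throwing version for bulk property loops: TRUE iff invariant holds.
coupling_holds <- function(td) {
  labs <- as.character(td$dat[[td$label]])
  trees <- if (inherits(td$phy, "phylo")) list(td$phy) else unclass(td$phy)
  all(vapply(trees, function(tr) setequal(labs, tr$tip.label), logical(1))) &&
    identical(labs, trees[[1]]$tip.label) &&
    nrow(td$dat) == length(trees[[1]]$tip.label)
}

# Small worked fixture: 6 taxa, two discrete and two continuous characters.
worked_fixture <- function() {
  tree <- parse_newick(
    "(((sp1:1,sp2:1):1,(sp3:1,sp4:1):1):1,(sp5:1,sp6:1):2);"
  )
  data <- data.frame(
    species = paste0("sp", 1:6),
    ecomorph = c("trunk", "trunk", "crown", "crown", "twig", "twig"),
    island = c("Cuba", "Cuba", "Hispaniola", "Hispaniola", "Cuba", "Jamaica"),
    SVL = c(50, 60, 40, 45, 55, 35),
    hostility = c(1, 2, 3, 4, 5, 6),
    stringsAsFactors = FALSE
  )
  list(tree = tree, data = data)
}

# Six-row discrete/continuous fixture for the filter + grouped aggregation.
aggregation_fixture <- function() {
  tree <- simulate_tree(6, seed = 99)
  data <- data.frame(
    species = tree$tip.label,
    Disc1 = c("A", "A", "B", "A", "B", "A"),
    Disc10 = c("X", "Y", "X", "X", "Y", "Y"),
    Cont2 = c(1, 2, 3, 4, 5, 6),
    Cont3 = c(2, 4, 6, 8, 10, 12),
    stringsAsFactors = FALSE
  )
  list(tree = tree, data = data)
}
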