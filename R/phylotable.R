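#' Couple trees to a trait table by taxon name
#'
#' Performs the one-time exact name match between the tip labels of one or
#' more trees and a taxon-label column of a character matrix, then returns a
#' coupled object in which the two are kept mutually consistent: the tip set
#' of every tree and the table's label column are always in bijection, and
#' rows are kept in the first tree's tip order.
#'
#' When `label_column` is `NULL` the column is chosen automatically: for
#' every column, the number of values occurring (exact, case-sensitive
#' string comparison) among the first tree's tip labels is counted, and the
#' column with the most matches wins (leftmost on ties, with a warning
#' naming the tied candidates).  The matched taxon set is the intersection
#' of that column's values with the tip sets of *all* trees — a tree-set is
#' forced to a common tip sampling — and every tree is pruned to it.
#' Unmatched rows are removed; duplicated taxon rows keep their first
#' occurrence.  The match is summarised in a report (`$report`) recording
#' the chosen column and all drop counts.
#'
#' @param tree A `"phylo"` object, `"multiPhylo"` object, or list of
#'   `"phylo"` trees.
#' @param data A data.frame or data.table with a header and one row per
#'   taxon.
#' @param label_column Optional name of the taxon-label column; `NULL`
#'   (default) selects it automatically as described above.
#' @return An object of class `"phylotable"`: a list with elements `phy`
#'   (tree or tree set), `dat` (a `data.table`, label column first), `label`
#'   (label column name), `report` (the match report) and cumulative drop
#'   counters.  Access components with `$phy`, `$dat`, [pull_phylotable()],
#'   or [extract_vector()].
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' d <- data.frame(species = c("A", "B", "D"), x = 1:3)
#' td <- as_phylotable(tr, d)
#' td$report
#' @export
as_phylotable <- function(tree, data, label_column = NULL) {
  trees <- as_treeset(tree)
  single <- inherits(tree, "phylo")
  for (tr in trees) validate_phylo(tr)
  if (!is.data.frame(data)) {
    stop_validation("'data' must be a data.frame or data.table")
  }
  dat <- as.data.table(data)
  if (ncol(dat) < 1L || nrow(dat) < 1L) {
    stop_validation("'data' must have at least one column and one row")
  }
  if (anyNA(names(dat)) || any(!nzchar(names(dat))) || anyDuplicated(names(dat))) {
    stop_validation("column names must be unique and non-empty (see force_names)")
  }

  tips1 <- trees[[1L]]$tip.label
  if (is.null(label_column)) {
    counts <- vapply(dat, function(col) {
      v <- as.character(col)
      sum(!is.na(v) & v %in% tips1)
    }, integer(1L))
    best <- max(counts)
    if (best == 0L) stop_validation("no overlap between tree and data")
    tied <- names(dat)[counts == best]
    if (length(tied) > 1L) {
      warning("label column tie between ",
              paste(sQuote(tied), collapse = ", "),
              "; using leftmost ", sQuote(tied[1L]))
    }
    label_column <- tied[1L]
  } else {
    if (!is.character(label_column) || length(label_column) != 1L ||
        !label_column %in% names(dat)) {
      stop_validation("label column ", sQuote(as.character(label_column)[1L]),
                      " not found in data")
    }
  }

  labs <- as.character(dat[[label_column]])
  common_tips <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  matched <- intersect(unique(labs[!is.na(labs)]), common_tips)
  if (length(matched) == 0L) {
    stop_validation("no overlap between tree and data")
  }
  if (length(matched) < 2L) {
    stop_validation("fewer than 2 taxa are shared between tree(s) and data")
  }

  in_match <- !is.na(labs) & labs %in% matched
  dup <- in_match & duplicated(labs)
  keep_row <- in_match & !dup
  n_rows_dropped <- sum(!in_match)
  n_dup_dropped <- sum(dup)

  per_tree_dropped <- vapply(trees, function(tr) {
    length(tr$tip.label) - length(matched)
  }, integer(1L))
  trees <- lapply(trees, prune_tree, keep = matched)

  dat <- dat[keep_row]
  dat[[label_column]] <- as.character(dat[[label_column]])
  dat <- dat[match(trees[[1L]]$tip.label, dat[[label_column]])]
  data.table::setcolorder(dat, label_column)
  data.table::setattr(dat, "label", label_column)

  report <- structure(
    list(
      label_column = label_column,
      n_matched = length(matched),
      n_tips_dropped = sum(per_tree_dropped),
      n_rows_dropped = n_rows_dropped,
      n_duplicate_rows_dropped = n_dup_dropped,
      per_tree_tips_dropped = per_tree_dropped
    ),
    class = "phylotable_report"
  )

  new_phylotable(trees, single, dat, label_column, report,
                 dropped_tips = 0L, dropped_rows = 0L)
}

new_phylotable <- function(trees, single, dat, label, report,
                           dropped_tips, dropped_rows) {
  phy <- if (single && length(trees) == 1L) {
    trees[[1L]]
  } else {
    structure(trees, class = "multiPhylo")
  }
  structure(
    list(
      phy = phy,
      dat = dat,
      label = label,
      report = report,
      dropped_tips = as.integer(dropped_tips),
      dropped_rows = as.integer(dropped_rows)
    ),
    class = "phylotable"
  )
}

# -- internal accessors (user-facing `$` and `[[` are overloaded) -----------

ptb_dat <- function(x) .subset2(x, "dat")
ptb_label <- function(x) .subset2(x, "label")
ptb_phy <- function(x) .subset2(x, "phy")
ptb_report <- function(x) .subset2(x, "report")
ptb_trees <- function(x) as_treeset(.subset2(x, "phy"))
ptb_single <- function(x) inherits(.subset2(x, "phy"), "phylo")

#' Taxa of a coupled object
#'
#' Tip labels in the first tree's tip order (which is also the table's row
#' order).
#'
#' @param x A `"phylotable"` object.
#' @return Character vector of taxon labels.
#' @export
taxa <- function(x) {
  stopifnot(inherits(x, "phylotable"))
  ptb_trees(x)[[1L]]$tip.label
}

# Rebuild a coupled object after rows/tips changed: prune all trees to the
# labels present in `dat`, reorder rows to the first tree's tip order, and
# bump the cumulative drop counters.
ptb_rebuild <- function(x, dat) {
  label <- ptb_label(x)
  labs <- as.character(dat[[label]])
  old_taxa <- taxa(x)
  removed <- length(old_taxa) - length(labs)
  trees <- lapply(ptb_trees(x), function(tr) {
    if (length(labs) == length(tr$tip.label)) tr else prune_tree(tr, labs)
  })
  dat <- dat[match(trees[[1L]]$tip.label, labs)]
  data.table::setcolorder(dat, label)
  data.table::setattr(dat, "label", label)
  new_phylotable(trees, ptb_single(x), dat, label, ptb_report(x),
                 dropped_tips = .subset2(x, "dropped_tips") + removed,
                 dropped_rows = .subset2(x, "dropped_rows") + removed)
}

#' Drop taxa from a coupled object
#'
#' Removes the named taxa from the table and from every tree (pruning with
#' branch-length merging); at least two taxa must remain.
#'
#' @param x A `"phylotable"` object.
#' @param labels Character vector of taxon labels to drop (may be empty).
#' @return A new `"phylotable"` with updated drop counters.
#' @export
drop_taxa <- function(x, labels) {
  stopifnot(inherits(x, "phylotable"))
  labels <- unique(as.character(labels))
  if (length(labels) == 0L) return(x)
  cur <- taxa(x)
  unknown <- setdiff(labels, cur)
  if (length(unknown) > 0L) {
    stop_validation("unknown taxon label(s): ",
                    paste(sQuote(unknown), collapse = ", "))
  }
  if (length(cur) - length(labels) < 2L) {
    stop_validation("cannot reduce a coupled object below 2 taxa")
  }
  dat <- ptb_dat(x)
  keep <- !(as.character(dat[[ptb_label(x)]]) %in% labels)
  ptb_rebuild(x, dat[keep])
}

#' Data-table style queries on a coupled object
#'
#' `x[i, j, by]` forwards to \pkg{data.table} on (a copy of) the character
#' matrix and then re-establishes the tree/table coupling.  If every output
#' row still corresponds to exactly one taxon — a pure row filter, a per-row
#' derived column, a `head(.SD, n)`-style per-group selection, or a `:=`
#' update — the taxon-label column is implicitly retained, every tree is
#' pruned to the surviving taxa, and a `"phylotable"` is returned.  If the
#' rows are collapsed by aggregation so that no row-to-taxon bijection
#' exists, the result is returned as a detached `data.table` with a warning.
#' Results that are not tables at all (e.g. `x[, sum(col)]`) are returned
#' as computed.
#'
#' @param x A `"phylotable"` object.
#' @param ... `i`, `j`, `by`/`keyby` and further arguments with
#'   \pkg{data.table} `[i, j, by]` semantics.
#' @return A `"phylotable"`, or a detached `data.table` (with a warning),
#'   or the raw value of `j`.
#' @examples
#' td <- as_phylotable(
#'   parse_newick("((sp1:1,sp2:1):1,sp3:2);"),
#'   data.frame(species = c("sp1", "sp2", "sp3"),
#'              island = c("Cuba", "Cuba", "Hispaniola"),
#'              SVL = c(50, 60, 40), hostility = c(1, 2, 3))
#' )
#' td[island == "Cuba", .(Index = SVL + hostility)]
#' @export
`[.phylotable` <- function(x, ...) {
  parts <- ptb_parse_bracket(sys.call(), parent.frame())
  dat <- data.table::copy(ptb_dat(x))
  ev <- new.env(parent = parts$env)
  assign("..ptb_dat..", dat, envir = ev)
  res <- eval(parts$call, ev)
  ptb_recouple(x, res, parts, ev)
}

# Decompose `x[...]` into i / j / by pieces and a rewritten data.table call.
ptb_parse_bracket <- function(cl, env) {
  args <- as.list(cl)[-c(1L, 2L)]
  nm <- names(args)
  if (is.null(nm)) nm <- rep("", length(args))
  # NB: a skipped positional slot (as in x[, j]) is the empty symbol, which
  # errors if ever evaluated through a variable; test it in place.
  i <- NULL; j <- NULL; by <- NULL; by_name <- "by"; extra <- list()
  pos <- 0L
  for (k in seq_along(args)) {
    miss <- identical(args[[k]], quote(expr = ))
    if (nm[k] == "") {
      pos <- pos + 1L
      if (pos == 1L) {
        if (!miss) i <- args[[k]]
      } else if (pos == 2L) {
        if (!miss) j <- args[[k]]
      } else {
        stop_validation("too many positional arguments in '['")
      }
    } else if (nm[k] == "i") {
      if (!miss) i <- args[[k]]
    } else if (nm[k] == "j") {
      if (!miss) j <- args[[k]]
    } else if (nm[k] %in% c("by", "keyby")) {
      by <- args[[k]]
      by_name <- nm[k]
    } else {
      extra[[nm[k]]] <- args[[k]]
    }
  }
  list(i = i, j = j, by = by, by_name = by_name, extra = extra, env = env,
       call = ptb_build_dt_call(i, j, by, by_name, extra))
}

ptb_build_dt_call <- function(i, j, by, by_name, extra) {
  argl <- list()
  argl$i <- i %||% quote(expr = )
  if (!is.null(j)) argl$j <- j
  if (!is.null(by)) argl[[by_name]] <- by
  argl <- c(argl, extra)
  as.call(c(list(as.name("["), as.name("..ptb_dat..")), argl))
}

# Decide coupled vs detached and assemble the result.
ptb_recouple <- function(x, res, parts, ev) {
  if (!is.data.frame(res)) return(res)
  res <- as.data.table(res)
  label <- ptb_label(x)
  cur <- taxa(x)

  labs <- NULL
  if (label %in% names(res)) {
    labs <- as.character(res[[label]])
  } else if (!is.null(parts$j)) {
    # per-row derivation without the label column: re-run with j replaced by
    # the label; identical i/by reproduce the result's row order iff j was
    # per-row, which we verify by comparing row counts
    trace_j <- as.call(list(quote(list),
                            ..ptb_lab.. = as.name(label)))
    tcall <- ptb_build_dt_call(parts$i, trace_j, parts$by, parts$by_name,
                               list())
    trace <- tryCatch(eval(tcall, ev), error = function(e) NULL)
    if (!is.null(trace) && nrow(trace) == nrow(res)) {
      labs <- as.character(trace[["..ptb_lab.."]])
    }
  }

  if (is.null(labs) || anyDuplicated(labs) || anyNA(labs) ||
      !all(labs %in% cur)) {
    warning("query result has no row-to-taxon bijection; ",
            "returning a detached table without trees")
    return(res[])
  }
  if (length(labs) < 2L) {
    stop_validation("query would leave fewer than 2 taxa")
  }
  if (!label %in% names(res)) {
    res <- cbind(data.table::setnames(data.table::data.table(labs), label),
                 res)
  }
  ptb_rebuild(x, res)
}

#' Extract named trait vectors
#'
#' Returns, for each requested trait, a vector of its values named by taxon
#' label in the first tree's tip order — the input format expected by most
#' comparative-method functions.
#'
#' @param x A `"phylotable"` object.
#' @param ... One or more column names (character), excluding the label
#'   column.
#' @return For a single trait, a named vector; for several, a named list of
#'   named vectors.
#' @examples
#' # extract_vector(td, "SVL", "ecomorph")
#' @export
extract_vector <- function(x, ...) {
  stopifnot(inherits(x, "phylotable"))
  traits <- unlist(list(...), use.names = FALSE)
  if (length(traits) == 0L || !is.character(traits)) {
    stop_validation("supply one or more trait names as character strings")
  }
  dat <- ptb_dat(x)
  label <- ptb_label(x)
  bad <- setdiff(traits, setdiff(names(dat), label))
  if (length(bad) > 0L) {
    stop_validation("unknown trait column(s): ",
                    paste(sQuote(bad), collapse = ", "))
  }
  labs <- as.character(dat[[label]])
  out <- lapply(traits, function(tr) setNames(dat[[tr]], labs))
  names(out) <- traits
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname extract_vector
#' @param i A single trait name (for the `[[` form).
#' @export
`[[.phylotable` <- function(x, i) {
  extract_vector(x, i)
}

#' @export
`$.phylotable` <- function(x, name) {
  switch(name,
         dat = , data = , table = data.table::copy(ptb_dat(x)),
         phy = , tree = , trees = ptb_phy(x),
         label = ptb_label(x),
         report = ptb_report(x),
         dropped_tips = .subset2(x, "dropped_tips"),
         dropped_rows = .subset2(x, "dropped_rows"),
         NULL)
}

#' Pull the table or the trees out of a coupled object
#'
#' Returns an independent copy: mutating the result does not affect `x`.
#'
#' @param x A `"phylotable"` object.
#' @param what `"table"` or `"trees"`.
#' @return A `data.table` (with the `"label"` attribute set) or the tree
#'   object (`"phylo"`/`"multiPhylo"`).
#' @export
pull_phylotable <- function(x, what = c("table", "trees")) {
  stopifnot(inherits(x, "phylotable"))
  what <- match.arg(what)
  if (what == "table") data.table::copy(ptb_dat(x)) else ptb_phy(x)
}

#' Run an external function on the coupled tree and table
#'
#' Passes each tree together with (a copy of) the character matrix to a
#' caller-supplied function — typically a comparative-method fit from
#' another package.  With a single tree the function's value is returned;
#' with a tree set it is applied per tree and the results are returned as a
#' list in tree order.  Errors raised by `fn` propagate with the tree index
#' prepended to the message.
#'
#' @param x A `"phylotable"` object.
#' @param fn A function of `(tree, data)`.
#' @return The value of `fn`, or a list of values (one per tree).
#' @examples
#' # apply_treedata(td, function(tree, data) ape::Ntip(tree))
#' @export
apply_treedata <- function(x, fn) {
  stopifnot(inherits(x, "phylotable"))
  if (!is.function(fn)) stop_validation("'fn' must be a function")
  trees <- ptb_trees(x)
  run1 <- function(idx) {
    tryCatch(
      fn(trees[[idx]], data.table::copy(ptb_dat(x))),
      error = function(e) {
        e$message <- sprintf("[tree %d] %s", idx, conditionMessage(e))
        stop(e)
      }
    )
  }
  if (ptb_single(x)) run1(1L) else lapply(seq_along(trees), run1)
}

#' Summarise a coupled object
#'
#' Counts taxa, trees, discrete and continuous characters (via
#' [detect_all_characters()]), missing cells in non-label columns, the
#' cumulative tips/rows dropped since construction, and echoes the initial
#' match report.
#'
#' @param object A `"phylotable"` object.
#' @param cutoff Passed to [detect_all_characters()].
#' @param ... Ignored.
#' @return A `"summary.phylotable"` list (printed nicely).
#' @export
summary.phylotable <- function(object, cutoff = 0.1, ...) {
  dat <- ptb_dat(object)
  label <- ptb_label(object)
  types <- detect_all_characters(dat, cutoff = cutoff, label_column = label)
  cols <- setdiff(names(dat), label)
  missing_cells <- sum(vapply(cols, function(cn) sum(is.na(dat[[cn]])),
                              integer(1L)))
  structure(
    list(
      n_taxa = nrow(dat),
      n_trees = length(ptb_trees(object)),
      n_discrete = sum(types == "discrete"),
      n_continuous = sum(types == "continuous"),
      n_missing = missing_cells,
      dropped_tips_total = .subset2(object, "dropped_tips"),
      dropped_rows_total = .subset2(object, "dropped_rows"),
      report = ptb_report(object)
    ),
    class = "summary.phylotable"
  )
}

#' @export
print.summary.phylotable <- function(x, ...) {
  cat("Coupled tree/data summary\n")
  cat(sprintf("  taxa: %d   trees: %d\n", x$n_taxa, x$n_trees))
  cat(sprintf("  characters: %d discrete, %d continuous\n",
              x$n_discrete, x$n_continuous))
  cat(sprintf("  missing values: %d\n", x$n_missing))
  cat(sprintf("  dropped since construction: %d tips, %d rows\n",
              x$dropped_tips_total, x$dropped_rows_total))
  print(x$report)
  invisible(x)
}

#' @export
print.phylotable_report <- function(x, ...) {
  cat(sprintf(
    "Match report: label column '%s'; %d taxa matched; %d tips, %d rows, %d duplicate rows dropped\n",
    x$label_column, x$n_matched, x$n_tips_dropped, x$n_rows_dropped,
    x$n_duplicate_rows_dropped
  ))
  if (length(x$per_tree_tips_dropped) > 1L) {
    cat("  tips dropped per tree:",
        paste(x$per_tree_tips_dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.phylotable <- function(x, n = 6L, ...) {
  trees <- ptb_trees(x)
  cat(sprintf(
    "A coupled tree/data object: %d taxa, %d tree%s (%d tips, %d internal nodes each)\n",
    nrow(ptb_dat(x)), length(trees), if (length(trees) == 1L) "" else "s",
    length(trees[[1L]]$tip.label), trees[[1L]]$Nnode
  ))
  cat(sprintf("Label column: '%s'\n", ptb_label(x)))
  print(head(ptb_dat(x), n))
  if (nrow(ptb_dat(x)) > n) {
    cat(sprintf("# ... %d more row(s)\n", nrow(ptb_dat(x)) - n))
  }
  invisible(x)
}

ptb_peek <- function(x, which, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_validation("'n' must be a single integer >= 1")
  }
  dat <- ptb_dat(x)
  rows <- if (which == "head") head(dat, n) else tail(dat, n)
  trees <- ptb_trees(x)
  lines <- c(
    capture.output(print(rows)),
    sprintf("%d tree%s with %d tips and %d internal nodes",
            length(trees), if (length(trees) == 1L) "" else "s",
            length(trees[[1L]]$tip.label), trees[[1L]]$Nnode)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Peek at the first or last rows of a coupled object
#'
#' Non-mutating: renders the first (`head`) or last (`tail`) `n` rows of the
#' character matrix plus a one-line tree summary.
#'
#' @param x A `"phylotable"` object.
#' @param n Number of rows to show.
#' @param ... Ignored.
#' @return The rendered lines, invisibly.
#' @export
head.phylotable <- function(x, n = 6L, ...) ptb_peek(x, "head", n)

#' @rdname head.phylotable
#' @export
tail.phylotable <- function(x, n = 6L, ...) ptb_peek(x, "tail", n)
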