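#' Parse Newick text into phylogenetic trees
#'
#' Reads one or more semicolon-terminated Newick statements into `"phylo"`
#' objects (as used by the \pkg{ape} ecosystem).  Labels are taken literally:
#' no underscore-to-space translation is performed, and single-quoted labels
#' are stored without their quotes (a doubled `''` inside quotes encodes a
#' literal quote).  Branch lengths follow `:` and may use scientific
#' notation.  Internal node labels are parsed and preserved (`node.label`),
#' and a length on the root group becomes `root.edge`.
#'
#' Malformed input raises a parse error reporting the character offset of the
#' offending token; duplicate tip labels within one tree, negative branch
#' lengths, or fewer than two tips raise validation errors.
#'
#' @param text A single character string holding one or more Newick
#'   statements, separated by semicolons (newlines between trees optional).
#' @param simplify If `TRUE` (default) a single tree is returned as a
#'   `"phylo"` object; otherwise (and always for multi-tree input) a
#'   `"multiPhylo"` list is returned, preserving file order.
#' @return A `"phylo"` or `"multiPhylo"` object.
#' @seealso [write_newick()], [read_newick()]
#' @examples
#' parse_newick("((A:1,B:2):3,C:4);")
#' parse_newick("('sp one':1,B:2);")$tip.label
#' @export
parse_newick <- function(text, simplify = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_validation("'text' must be a single character string")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- 1L
  ws <- c(" ", "\t", "\n", "\r")
  meta <- c("(", ")", ",", ":", ";")

  skip_ws <- function() {
    while (pos <= n && chars[pos] %in% ws) pos <<- pos + 1L
  }
  # A label: quoted ('' escapes a quote) or bare (up to metachar/whitespace).
  read_label <- function() {
    if (pos <= n && chars[pos] == "'") {
      start <- pos
      pos <<- pos + 1L
      out <- character(0L)
      repeat {
        if (pos > n) {
          stop_parse("unterminated quoted label starting at character ", start)
        }
        ch <- chars[pos]
        if (ch == "'") {
          if (pos + 1L <= n && chars[pos + 1L] == "'") {
            out <- c(out, "'")
            pos <<- pos + 2L
          } else {
            pos <<- pos + 1L
            break
          }
        } else {
          out <- c(out, ch)
          pos <<- pos + 1L
        }
      }
      paste(out, collapse = "")
    } else {
      start <- pos
      while (pos <= n && !(chars[pos] %in% meta) && !(chars[pos] %in% ws)) {
        pos <<- pos + 1L
      }
      if (pos > start) paste(chars[start:(pos - 1L)], collapse = "") else ""
    }
  }
  read_length <- function() {
    # caller consumed ':'
    skip_ws()
    start <- pos
    while (pos <= n && grepl("[0-9.eE+-]", chars[pos])) pos <<- pos + 1L
    tok <- if (pos > start) paste(chars[start:(pos - 1L)], collapse = "") else ""
    val <- suppressWarnings(as.numeric(tok))
    if (tok == "" || is.na(val)) {
      stop_parse("expected a branch length after ':' at character ", start)
    }
    val
  }

  # Flat node records, assigned in creation (preorder) order.
  # An internal node is created at its '(', a tip at its label.
  new_tree_state <- function() {
    list(
      is_tip = logical(0L), label = character(0L), length = numeric(0L),
      parent = integer(0L)
    )
  }

  trees <- list()
  repeat {
    skip_ws()
    if (pos > n) break
    st <- new_tree_state()
    n_nodes <- 0L
    add_node <- function(is_tip, parent) {
      n_nodes <<- n_nodes + 1L
      st$is_tip[n_nodes] <<- is_tip
      st$label[n_nodes] <<- ""
      st$length[n_nodes] <<- NA_real_
      st$parent[n_nodes] <<- parent
      n_nodes
    }
    frame_node <- integer(0L)   # stack: serial of open internal node
    frame_open <- integer(0L)   # stack: source offset of its '('
    completed <- NA_integer_    # serial of the clade just finished, or NA
    root_serial <- NA_integer_

    repeat {
      skip_ws()
      if (pos > n) {
        if (length(frame_open) > 0L) {
          stop_parse(
            "unbalanced parentheses: '(' at character ",
            frame_open[length(frame_open)], " is never closed"
          )
        }
        stop_parse("unexpected end of input: missing ';'")
      }
      ch <- chars[pos]
      if (is.na(completed)) {
        # expecting the start of a clade: '(' or a tip label
        if (ch == "(") {
          parent <- if (length(frame_node)) frame_node[length(frame_node)] else 0L
          id <- add_node(FALSE, parent)
          frame_node <- c(frame_node, id)
          frame_open <- c(frame_open, pos)
          pos <- pos + 1L
        } else if (ch %in% meta) {
          stop_parse("unexpected '", ch, "' at character ", pos)
        } else {
          at <- pos
          lab <- read_label()
          if (!nzchar(lab)) {
            stop_parse("expected a tip label at character ", at)
          }
          parent <- if (length(frame_node)) frame_node[length(frame_node)] else 0L
          id <- add_node(TRUE, parent)
          st$label[id] <- lab
          skip_ws()
          if (pos <= n && chars[pos] == ":") {
            pos <- pos + 1L
            st$length[id] <- read_length()
          }
          completed <- id
        }
      } else {
        # a clade is in hand: expect ',' ')' or ';'
        if (ch == ",") {
          if (length(frame_node) == 0L) {
            stop_parse("unexpected ',' at character ", pos,
                       " (not inside parentheses)")
          }
          completed <- NA_integer_
          pos <- pos + 1L
        } else if (ch == ")") {
          if (length(frame_node) == 0L) {
            stop_parse("unbalanced parentheses: unexpected ')' at character ",
                       pos)
          }
          id <- frame_node[length(frame_node)]
          frame_node <- frame_node[-length(frame_node)]
          frame_open <- frame_open[-length(frame_open)]
          pos <- pos + 1L
          skip_ws()
          lab <- read_label()   # optional internal label ("" if none)
          st$label[id] <- lab
          skip_ws()
          if (pos <= n && chars[pos] == ":") {
            pos <- pos + 1L
            st$length[id] <- read_length()
          }
          completed <- id
        } else if (ch == ";") {
          if (length(frame_node) > 0L) {
            stop_parse(
              "unbalanced parentheses: '(' at character ",
              frame_open[length(frame_open)], " is never closed"
            )
          }
          root_serial <- completed
          pos <- pos + 1L
          break
        } else {
          stop_parse("unexpected '", ch, "' at character ", pos)
        }
      }
    }
    st$is_tip <- st$is_tip[seq_len(n_nodes)]
    st$label <- st$label[seq_len(n_nodes)]
    st$length <- st$length[seq_len(n_nodes)]
    st$parent <- st$parent[seq_len(n_nodes)]
    trees[[length(trees) + 1L]] <- records_to_phylo(st, root_serial)
  }

  if (length(trees) == 0L) stop_parse("empty input: no Newick statement found")
  for (tr in trees) validate_phylo(tr)
  if (length(trees) == 1L && simplify) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  trees
}

# Convert flat preorder node records to an ape "phylo" object.
records_to_phylo <- function(st, root_serial) {
  n_tip <- sum(st$is_tip)
  if (n_tip < 2L) {
    stop_validation("tree has fewer than 2 tips")
  }
  # phylo ids: tips 1..n_tip in serial (= left-to-right) order, internal
  # nodes n_tip+1.. in serial (= preorder) order
  id <- integer(length(st$is_tip))
  id[st$is_tip] <- seq_len(n_tip)
  id[!st$is_tip] <- n_tip + seq_len(sum(!st$is_tip))

  if (sum(!st$is_tip) == 0L) {
    # single bare pair like "A:1,B:2;" cannot occur (needs parens); guard
    stop_parse("tree has no internal node")
  }

  child_serial <- which(st$parent > 0L)
  edge <- cbind(id[st$parent[child_serial]], id[child_serial])
  edge_len <- st$length[child_serial]
  k <- nrow(edge)

  # reorder edges cladewise (preorder, source sibling order preserved)
  n_node <- sum(!st$is_tip)
  rows_by_parent <- split(seq_len(k), factor(edge[, 1L],
                                             levels = seq_len(n_tip + n_node)))
  ord <- integer(k)
  filled <- 0L
  work <- rev(rows_by_parent[[n_tip + 1L]])   # root is first internal node
  while (length(work) > 0L) {
    r <- work[length(work)]
    work <- work[-length(work)]
    filled <- filled + 1L
    ord[filled] <- r
    rows <- rows_by_parent[[edge[r, 2L]]]
    if (length(rows) > 0L) work <- c(work, rev(rows))
  }
  edge <- edge[ord, , drop = FALSE]
  edge_len <- edge_len[ord]

  phy <- list(
    edge = edge,
    Nnode = n_node,
    tip.label = st$label[st$is_tip]
  )
  if (any(!is.na(edge_len))) phy$edge.length <- edge_len
  node_lab <- st$label[!st$is_tip]
  if (any(nzchar(node_lab))) phy$node.label <- node_lab
  root_len <- st$length[root_serial]
  if (!is.na(root_len)) phy$root.edge <- root_len
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

validate_phylo <- function(phy) {
  labs <- phy$tip.label
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    stop_validation("duplicate tip label(s): ",
                    paste(sQuote(dup), collapse = ", "))
  }
  if (any(!nzchar(labs)) || anyNA(labs)) {
    stop_validation("tip labels must be non-empty strings")
  }
  bl <- c(phy$edge.length, phy$root.edge)
  if (!is.null(bl) && any(!is.na(bl) & bl < 0)) {
    stop_validation("negative branch length(s) are not allowed")
  }
  invisible(phy)
}

#' Read Newick trees from a file
#'
#' @param file Path to a Newick file holding one or more trees.
#' @inheritParams parse_newick
#' @return A `"phylo"` or `"multiPhylo"` object.
#' @export
read_newick <- function(file, simplify = TRUE) {
  if (!file.exists(file)) stop_validation("file not found: ", file)
  parse_newick(paste(readLines(file, warn = FALSE), collapse = "\n"),
               simplify = simplify)
}

#' Write trees as Newick text
#'
#' Serialises `"phylo"` / `"multiPhylo"` objects, one semicolon-terminated
#' statement per tree.  Labels containing Newick metacharacters
#' (`( ) , : ;`), quotes, or whitespace are single-quoted (with `''` escaping
#' an embedded quote); all other labels are written literally, so the output
#' re-parses to the same labels.  Branch lengths are rounded to `digits`
#' significant digits.
#'
#' @param trees A `"phylo"` object, a `"multiPhylo"` object, or a list of
#'   `"phylo"` objects.
#' @param file Optional path; when given the text is written there and
#'   returned invisibly.
#' @param digits Significant digits for branch lengths (>= 1).
#' @return A character vector, one Newick statement per tree.
#' @seealso [parse_newick()]
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' write_newick(tr)
#' @export
write_newick <- function(trees, file = NULL, digits = 10L) {
  if (!is.numeric(digits) || length(digits) != 1L || digits < 1) {
    stop_validation("'digits' must be a single number >= 1")
  }
  trees <- as_treeset(trees)
  out <- vapply(trees, newick_one, character(1L), digits = as.integer(digits))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

newick_fmt_label <- function(lab) {
  if (is.na(lab) || !nzchar(lab)) return("")
  if (grepl("[](),:;'\"[[:space:]]", lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else {
    lab
  }
}

newick_one <- function(phy, digits) {
  if (!inherits(phy, "phylo")) stop_validation("not a 'phylo' object")
  n_tip <- length(phy$tip.label)
  edge <- phy$edge
  k <- nrow(edge)
  n_all <- n_tip + phy$Nnode
  len_by_node <- rep(NA_real_, n_all)
  if (!is.null(phy$edge.length)) len_by_node[edge[, 2L]] <- phy$edge.length
  node_lab <- rep("", n_all)
  node_lab[seq_len(n_tip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    node_lab[n_tip + seq_len(phy$Nnode)] <- phy$node.label
  }
  fmt_len <- function(node) {
    x <- len_by_node[node]
    if (is.na(x)) "" else paste0(":", as.character(signif(x, digits)))
  }
  rows_by_parent <- split(seq_len(k), factor(edge[, 1L], levels = seq_len(n_all)))
  root <- n_tip + 1L
  # iterative depth-first rendering (explicit stack; deep trees safe)
  pieces <- character(0L)
  np <- 0L
  emit <- function(s) {
    np <<- np + 1L
    if (np > length(pieces)) pieces <<- c(pieces, character(max(64L, np)))
    pieces[np] <<- s
  }
  st_node <- integer(0L)
  st_next <- integer(0L)
  push <- function(node) {
    st_node <<- c(st_node, node)
    st_next <<- c(st_next, 1L)
    emit("(")
  }
  push(root)
  while (length(st_node) > 0L) {
    top <- length(st_node)
    node <- st_node[top]
    ci <- st_next[top]
    rows <- rows_by_parent[[node]]
    if (ci <= length(rows)) {
      st_next[top] <- ci + 1L
      if (ci > 1L) emit(",")
      child <- edge[rows[ci], 2L]
      if (child <= n_tip) {
        emit(paste0(newick_fmt_label(node_lab[child]), fmt_len(child)))
      } else {
        push(child)
      }
    } else {
      st_node <- st_node[-top]
      st_next <- st_next[-top]
      emit(paste0(")", newick_fmt_label(node_lab[node]), fmt_len(node)))
    }
  }
  root_part <- if (!is.null(phy$root.edge)) {
    paste0(":", as.character(signif(phy$root.edge, digits)))
  } else ""
  paste0(paste(pieces[seq_len(np)], collapse = ""), root_part, ";")
}

# Normalize phylo / multiPhylo / list-of-phylo to a plain list of phylo.
as_treeset <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  if (is.list(trees) && length(trees) > 0L &&
      all(vapply(trees, inherits, logical(1L), what = "phylo"))) {
    return(trees)
  }
  stop_validation(
    "expected a 'phylo' object, a 'multiPhylo' object, or a list of 'phylo'"
  )
}
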