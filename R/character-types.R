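#' Classify a character as discrete or continuous
#'
#' Non-numeric columns are discrete.  A column that is numeric (or a
#' character column whose every non-missing value parses strictly as a
#' number) is classified by the ratio of distinct non-missing values to
#' non-missing values: below `cutoff` it is discrete, otherwise continuous.
#' Numeric-looking strings in a column that does not parse fully are left
#' alone (discrete): no silent coercion.
#'
#' @param values A vector (one column of a trait table) with at least one
#'   non-missing value.
#' @param cutoff Distinct-value ratio threshold in (0, 1]; default 0.1.
#' @return `"discrete"` or `"continuous"`.
#' @examples
#' detect_character_type(rnorm(100))                 # continuous
#' detect_character_type(c("A", "B", "A", "B"))      # discrete
#' detect_character_type(sample(c(0, 1), 100, TRUE)) # discrete (ratio 0.02)
#' @export
detect_character_type <- function(values, cutoff = 0.1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1) {
    stop_validation("'cutoff' must be a single number in (0, 1]")
  }
  if (is.factor(values)) values <- as.character(values)
  vals <- values[!is.na(values)]
  if (length(vals) == 0L) stop_validation("all values are missing")
  if (is.character(vals)) {
    parsed <- suppressWarnings(as.numeric(vals))
    if (anyNA(parsed)) return("discrete")
    vals <- parsed
  } else if (is.logical(vals)) {
    return("discrete")
  } else if (!is.numeric(vals)) {
    return("discrete")
  }
  ratio <- length(unique(vals)) / length(vals)
  if (ratio < cutoff) "discrete" else "continuous"
}

#' Classify every character in a trait table
#'
#' Applies [detect_character_type()] to each non-label column.
#'
#' @param tab A data.frame/data.table or a [phylotable] object.
#' @param cutoff Passed to [detect_character_type()].
#' @param label_column Taxon-label column to exclude; defaults to the table's
#'   `"label"` attribute (or the coupled object's label column).
#' @return Named character vector mapping column name to `"discrete"` or
#'   `"continuous"` (empty if there are no non-label columns).
#' @export
detect_all_characters <- function(tab, cutoff = 0.1, label_column = NULL) {
  r <- resolve_table(tab, label_column)
  cols <- setdiff(names(r$tab), r$label)
  out <- vapply(cols, function(cn) {
    tryCatch(
      detect_character_type(r$tab[[cn]], cutoff = cutoff),
      error = function(e) {
        stop_validation("column ", sQuote(cn), ": ", conditionMessage(e))
      }
    )
  }, character(1L))
  out
}

#' Filter a trait table by character type
#'
#' Keeps only columns of the requested type, in their original order; the
#' taxon-label column (when designated) is always retained, first.
#'
#' @param tab A data.frame/data.table or a [phylotable] object (its table is
#'   filtered and returned detached).
#' @param keep `"continuous"` or `"discrete"`.
#' @inheritParams detect_all_characters
#' @return A `data.table` (label column plus matching columns; possibly
#'   label-only).
#' @export
filter_matrix <- function(tab, keep = c("continuous", "discrete"),
                          cutoff = 0.1, label_column = NULL) {
  keep <- match.arg(keep)
  r <- resolve_table(tab, label_column)
  types <- detect_all_characters(r$tab, cutoff = cutoff, label_column = r$label)
  cols <- names(types)[types == keep]
  out <- r$tab[, c(r$label, cols), with = FALSE]
  if (!is.null(r$label)) data.table::setattr(out, "label", r$label)
  out
}

#' Check row/column names of a trait table
#'
#' The columns check is `TRUE` when every column has a non-empty, unique
#' name; the rows check is `TRUE` when a taxon-label column is designated
#' (the `"label"` attribute or `label_column`) and its values are unique,
#' non-missing strings; `"both"` is their conjunction.
#'
#' @param tab A data.frame/data.table or a [phylotable] object.
#' @param which `"rows"`, `"columns"` or `"both"`.
#' @inheritParams detect_all_characters
#' @return A logical scalar.
#' @export
has_names <- function(tab, which = c("both", "rows", "columns"),
                      label_column = NULL) {
  which <- match.arg(which)
  r <- resolve_table(tab, label_column)
  cols_ok <- function() {
    nm <- names(r$tab)
    length(nm) == ncol(r$tab) && !anyNA(nm) && all(nzchar(nm)) &&
      !anyDuplicated(nm)
  }
  rows_ok <- function() {
    if (is.null(r$label)) return(FALSE)
    v <- r$tab[[r$label]]
    !anyNA(v) && !anyDuplicated(v)
  }
  switch(which,
         columns = cols_ok(),
         rows = rows_ok(),
         both = cols_ok() && rows_ok())
}

#' Force row/column names on a trait table
#'
#' Missing or empty column names are replaced by `V<position>` (then
#' deduplicated if needed).  A missing taxon-label designation is resolved by
#' designating the first character column whose values are unique and
#' non-missing; when no such column exists, a new `taxon` column with labels
#' `taxon_1..taxon_n` is prepended.  Idempotent.
#'
#' @inheritParams has_names
#' @return A `data.table` with valid names and (for `"rows"`/`"both"`) a
#'   `"label"` attribute naming the taxon-label column.
#' @export
force_names <- function(tab, which = c("both", "rows", "columns"),
                        label_column = NULL) {
  which <- match.arg(which)
  r <- resolve_table(tab, label_column)
  out <- data.table::copy(r$tab)
  lab <- r$label
  if (which %in% c("columns", "both")) {
    nm <- names(out)
    bad <- is.na(nm) | !nzchar(nm)
    nm[bad] <- paste0("V", which(bad))
    nm <- make.unique(nm, sep = "_")
    data.table::setnames(out, nm)
    if (!is.null(lab) && !lab %in% nm) lab <- NULL
  }
  if (which %in% c("rows", "both")) {
    valid <- function(v) is.character(v) && !anyNA(v) && !anyDuplicated(v)
    if (is.null(lab) || !valid(out[[lab]])) {
      lab <- NULL
      for (cn in names(out)) {
        if (valid(out[[cn]])) { lab <- cn; break }
      }
      if (is.null(lab)) {
        lab <- if ("taxon" %in% names(out)) {
          make.unique(c(names(out), "taxon"), sep = "_")[ncol(out) + 1L]
        } else "taxon"
        out[, (lab) := paste0("taxon_", seq_len(.N))]
        data.table::setcolorder(out, lab)
      }
    }
  }
  if (!is.null(lab)) data.table::setattr(out, "label", lab)
  out[]
}
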