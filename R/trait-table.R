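#' Read a trait table from a delimited file
#'
#' Reads a CSV/TSV character matrix (header row required, one row per taxon)
#' into a `data.table`.  The delimiter is inferred from the file extension
#' (`.csv` comma, `.tsv`/`.tab` tab) unless given explicitly; empty cells and
#' `"NA"` are read as missing.
#'
#' @param file Path to the delimited file.
#' @param sep Optional single-character delimiter overriding the inference.
#' @param label_column Optional name of the taxon-label column; stored as the
#'   `"label"` attribute used by [has_names()], [filter_matrix()] and friends.
#' @return A `data.table`.
#' @export
read_trait_table <- function(file, sep = NULL, label_column = NULL) {
  if (!file.exists(file)) stop_validation("file not found: ", file)
  if (is.null(sep)) {
    ext <- tolower(tools::file_ext(file))
    sep <- switch(ext, csv = ",", tsv = "\t", tab = "\t", "auto")
  }
  tab <- data.table::fread(file, sep = sep, header = TRUE,
                           na.strings = c("", "NA"), data.table = TRUE)
  if (ncol(tab) < 1L || nrow(tab) < 1L) {
    stop_validation("trait table is empty: ", file)
  }
  if (!is.null(label_column)) {
    if (!label_column %in% names(tab)) {
      stop_validation("label column ", sQuote(label_column), " not found in ", file)
    }
    data.table::setattr(tab, "label", label_column)
  }
  tab
}

#' Write a trait table to a delimited file
#'
#' @param tab A data.frame or data.table.
#' @param file Output path; `.csv` writes comma-separated, anything else
#'   tab-separated unless `sep` is given.
#' @param sep Optional delimiter.
#' @return `file`, invisibly.
#' @export
write_trait_table <- function(tab, file, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (tolower(tools::file_ext(file)) == "csv") "," else "\t"
  }
  data.table::fwrite(as.data.table(tab), file, sep = sep)
  invisible(file)
}

# Resolve a table argument that may be a phylotable, data.table or data.frame.
# Returns list(tab = data.table, label = label column name or NULL).
resolve_table <- function(tab, label_column = NULL) {
  if (inherits(tab, "phylotable")) {
    return(list(tab = tab[["dat"]], label = tab[["label"]]))
  }
  if (!is.data.frame(tab)) {
    stop_validation("expected a data.frame, data.table or phylotable")
  }
  lab <- label_column %||% attr(tab, "label")
  if (!is.null(lab) && !lab %in% names(tab)) {
    stop_validation("label column ", sQuote(lab), " not found in table")
  }
  list(tab = as.data.table(tab), label = lab)
}
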