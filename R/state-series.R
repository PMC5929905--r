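#' Construct a state series
#'
#' A state series holds the multichannel recording of one experimental state:
#' a numeric matrix with time points in rows and labelled nodes in columns.
#' All downstream covariance summaries and the network pipeline consume this
#' container.
#'
#' @param values Numeric matrix, time points x nodes. Column names are used as
#'   node labels when `node_labels` is not given.
#' @param node_labels Character vector of unique node labels, one per column.
#' @param state_label Single string naming the state (e.g. `"A"`).
#'
#' @return An object of class `state_series`: a list with elements `values`
#'   (matrix with column names), `node_labels` and `state_label`.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("n1", "n2")))
#' s <- state_series(x, state_label = "A")
#' @export
state_series <- function(values, node_labels = colnames(values),
                         state_label = "A") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L)
    stop("a state series needs at least 2 time points", call. = FALSE)
  if (ncol(values) < 2L)
    stop("a state series needs at least 2 nodes", call. = FALSE)
  if (any(!is.finite(values)))
    stop("all values must be finite; missing values are not allowed",
         call. = FALSE)
  if (is.null(node_labels))
    node_labels <- paste0("node", seq_len(ncol(values)))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != ncol(values))
    stop("'node_labels' must have one entry per column", call. = FALSE)
  if (anyDuplicated(node_labels))
    stop("node labels must be unique", call. = FALSE)
  colnames(values) <- node_labels
  structure(
    list(values = values, node_labels = node_labels,
         state_label = as.character(state_label)[1]),
    class = "state_series"
  )
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("state series '%s': %d time points x %d nodes\n",
              x$state_label, nrow(x$values), length(x$node_labels)))
  cat("nodes:", paste(x$node_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a state series from a delimited text file
#'
#' Expects a header row of node labels and one row per time point, comma- or
#' tab-delimited (sniffed from the header line unless `sep` is given).
#'
#' @param path Path to the file.
#' @param state_label State name recorded on the result.
#' @param sep Field separator; `NULL` (default) tries comma then tab.
#' @param transpose If `TRUE` the file holds nodes in rows and time in
#'   columns, with the first column carrying node labels.
#' @return A [state_series()].
#' @export
read_state_series <- function(path, state_label = "A", sep = NULL,
                              transpose = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = !transpose, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (transpose) {
    labels <- as.character(df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    dimnames(m) <- list(NULL, labels)
  } else {
    m <- as.matrix(df)
  }
  if (!is.numeric(m)) {
    bad <- which(!vapply(as.data.frame(m), is.numeric, logical(1)))
    stop("non-numeric values in ", path, ", column(s): ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  }
  if (anyNA(m)) {
    bad_row <- which(rowSums(is.na(m)) > 0)[1]
    stop("missing value in ", path, " at data row ", bad_row, call. = FALSE)
  }
  state_series(m, state_label = state_label)
}

#' Write a state series to CSV
#'
#' @param series A [state_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_series <- function(series, path) {
  stopifnot(inherits(series, "state_series"))
  utils::write.csv(as.data.frame(series$values), path, row.names = FALSE)
  invisible(path)
}
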