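#' Construct a variables-by-objects data matrix
#'
#' The unit of analysis throughout this package: a numeric matrix whose rows
#' are the \emph{variables} used for clustering (e.g., genes or patients) and
#' whose columns are the \emph{objects} to be clustered. Missing values are
#' rejected outright: silent imputation would distort the correlation
#' structure that every downstream step depends on.
#'
#' @param values numeric matrix, variables in rows, objects in columns.
#' @param object_ids character vector of column labels (defaults to
#'   `colnames(values)` or `obj1, obj2, ...`).
#' @param variable_ids character vector of row labels (defaults to
#'   `rownames(values)` or `var1, var2, ...`).
#' @return An object of class `data_matrix`: a list with elements `values`,
#'   `object_ids` and `variable_ids`.
#' @examples
#' dm <- data_matrix(matrix(rnorm(40), 10, 4))
#' dim(dm$values)
#' @export
data_matrix <- function(values, object_ids = colnames(values),
                        variable_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("data matrix contains missing or non-finite values; ",
         "impute or remove them before analysis")
  }
  n <- nrow(values)
  P <- ncol(values)
  if (n < 2L || P < 2L) {
    stop("need at least 2 variables (rows) and 2 objects (columns), got ",
         n, " x ", P)
  }
  if (is.null(object_ids)) object_ids <- paste0("obj", seq_len(P))
  if (is.null(variable_ids)) variable_ids <- paste0("var", seq_len(n))
  object_ids <- as.character(object_ids)
  variable_ids <- as.character(variable_ids)
  if (length(object_ids) != P) stop("object_ids must have length ", P)
  if (length(variable_ids) != n) stop("variable_ids must have length ", n)
  dimnames(values) <- list(variable_ids, object_ids)
  structure(list(values = values,
                 object_ids = object_ids,
                 variable_ids = variable_ids),
            class = "data_matrix")
}

#' Coerce to a data matrix
#'
#' @param x a `data_matrix`, matrix, or data frame.
#' @param ... passed to [data_matrix()].
#' @return A `data_matrix`.
#' @export
as_data_matrix <- function(x, ...) {
  if (inherits(x, "data_matrix")) x else data_matrix(x, ...)
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("data_matrix:", nrow(x$values), "variables x", ncol(x$values),
      "objects\n")
  invisible(x)
}

#' Read a data matrix from a delimited text file
#'
#' Expects a header row of object ids and a first column of variable ids.
#' The `objects_in` flag transposes row-oriented files on ingestion so that
#' objects always end up in columns.
#'
#' @param path path to a CSV or TSV file.
#' @param objects_in `"columns"` (default) if the things to be clustered are
#'   the file's columns, `"rows"` if they are its rows.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` are tab-separated, anything else comma-separated).
#' @return A `data_matrix`.
#' @export
read_data_matrix <- function(path, objects_in = c("columns", "rows"),
                             sep = NULL) {
  objects_in <- match.arg(objects_in)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (objects_in == "rows") m <- t(m)
  data_matrix(m)
}

#' Standardize every variable to mean zero and unit standard deviation
#'
#' Each row (variable) is centred and scaled across the objects. A constant
#' row carries no information about the objects and makes the scaling
#' undefined, so it is an error rather than being silently dropped.
#'
#' @param data a `data_matrix` (or coercible).
#' @return A standardized `data_matrix`.
#' @export
standardize <- function(data) {
  data <- as_data_matrix(data)
  x <- data$values
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1))
  zero <- s < 1e-12
  if (any(zero)) {
    stop("zero-variance variable(s): ",
         paste(utils::head(data$variable_ids[zero], 5L), collapse = ", "))
  }
  out <- data
  out$values <- xc / s
  attr(out, "standardized") <- TRUE
  out
}
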