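#' Assemble a regression dataset
#'
#' Bundles a numeric response vector and a numeric predictor matrix into the
#' container used by every other function in the package, enforcing the input
#' contract: no missing values, at least 3 cases, between 1 and `cap`
#' predictors, unique variable names.
#'
#' The default cap of 31 predictors (32 variable columns including the
#' response) mirrors the historical limit of branch-and-bound subset-search
#' implementations; it is not intrinsic to the algorithm and can be raised,
#' though run time grows exponentially with the number of predictors.
#'
#' @param predictors Numeric matrix or data frame, one column per predictor.
#' @param response Numeric vector, one value per row of `predictors`.
#' @param response_name Label for the response variable.
#' @param cap Maximum number of predictors accepted (default 31).
#' @return An object of class `revs_data`: a list with elements `y`, `X`,
#'   `n`, `p`, `response_name`.
#' @examples
#' d <- revs_dataset(matrix(rnorm(40), 10, 4), rnorm(10))
#' d$p
#' @export
revs_dataset <- function(predictors, response, response_name = "y",
                         cap = 31L) {
  X <- as.matrix(predictors)
  if (!is.numeric(X)) stop("predictors must be numeric")
  y <- as.numeric(response)
  if (nrow(X) != length(y)) stop("response length must match predictor rows")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed; drop or impute rows first")
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("at least 3 cases are required")
  if (p < 1L) stop("at least 1 predictor is required")
  if (p > cap) {
    stop(sprintf(
      "dataset has %d predictors but the cap is %d (%d predictors and 1 dependent variable); raise `cap` to override",
      p, cap, cap))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  nm <- c(colnames(X), response_name)
  if (anyDuplicated(nm)) stop("variable names must be unique")
  structure(list(y = y, X = X, n = n, p = p, response_name = response_name),
            class = "revs_data")
}

#' @export
print.revs_data <- function(x, ...) {
  cat(sprintf("<revs_data> %d cases, %d predictors; response: %s\n",
              x$n, x$p, x$response_name))
  cat("predictors:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Read a regression dataset from CSV
#'
#' Reads a comma-separated file with a header row. The named response column
#' becomes the dependent variable and every remaining column a predictor.
#' Rows containing any missing value are dropped (with a message reporting the
#' count). Binary/categorical predictors must be pre-encoded as numeric 0/1
#' columns.
#'
#' @param path Path to a CSV file.
#' @param response Name of the response column.
#' @param cap Maximum number of predictors accepted (default 31).
#' @return A [revs_dataset()] object.
#' @export
read_dataset <- function(path, response, cap = 31L) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  if (!response %in% names(df)) {
    stop(sprintf("response column '%s' not found in %s", response, path))
  }
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  pred <- df[, setdiff(names(df), response), drop = FALSE]
  bad <- names(pred)[!vapply(pred, is.numeric, logical(1))]
  if (length(bad)) {
    stop(sprintf("non-numeric predictor column(s): %s; encode them numerically first",
                 paste(bad, collapse = ", ")))
  }
  revs_dataset(as.matrix(pred), df[[response]], response_name = response,
               cap = cap)
}

#' Write a regression dataset to CSV
#'
#' Inverse of [read_dataset()]: writes the response and predictors as one
#' header-row CSV, response column last.
#'
#' @param data A `revs_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "revs_data"))
  m <- cbind(data$X, data$y)
  colnames(m) <- c(colnames(data$X), data$response_name)
  # 17 significant digits so the numeric matrix round-trips to full precision
  cells <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m))
  lines <- c(paste(colnames(m), collapse = ","),
             apply(cells, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
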