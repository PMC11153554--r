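# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

as_numeric_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame", arg), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

check_finite <- function(x, arg = "x") {
  if (length(x) == 0L) {
    stop(sprintf("`%s` must be non-empty", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values (NA/NaN/Inf)", arg), call. = FALSE)
  }
  invisible(x)
}

#' Construct a regression dataset
#'
#' A lightweight container pairing a numeric feature matrix with an optional
#' numeric target vector, the common currency of all pipeline stages.
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param y Optional numeric target vector, one value per row of `x`.
#' @param feature_names Column names for the features; defaults to the
#'   matrix's column names or `x1..xp`.
#' @param target_name Name of the target variable.
#' @return An object of class `"dataset"` with elements `x`, `y`,
#'   `feature_names` and `target_name`.
#' @examples
#' d <- dataset(matrix(rnorm(20), 10, 2), rnorm(10))
#' nrow(d$x)
#' @export
dataset <- function(x, y = NULL, feature_names = NULL, target_name = "y") {
  x <- as_numeric_matrix(x, "x")
  check_finite(x, "x")
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(x)))
  }
  if (length(feature_names) != ncol(x)) {
    stop("`feature_names` length must match ncol(x)", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (!is.null(y)) {
    y <- as.numeric(y)
    check_finite(y, "y")
    if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)", call. = FALSE)
  }
  colnames(x) <- feature_names
  structure(
    list(x = x, y = y, feature_names = feature_names, target_name = target_name),
    class = "dataset"
  )
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf(
    "<dataset> %d rows x %d features (%s)%s\n",
    nrow(x$x), ncol(x$x),
    paste(utils::head(x$feature_names, 4L), collapse = ", "),
    if (is.null(x$y)) ", no target" else sprintf(", target '%s'", x$target_name)
  ))
  invisible(x)
}

# Subset a dataset by row indices.
dataset_rows <- function(d, idx) {
  dataset(d$x[idx, , drop = FALSE],
          if (is.null(d$y)) NULL else d$y[idx],
          feature_names = d$feature_names, target_name = d$target_name)
}
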