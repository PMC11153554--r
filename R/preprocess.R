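#' Fit a max-abs scaler
#'
#' Records the per-column maximum absolute value of the training matrix;
#' scaling divides each column by it, mapping training columns into
#' \[-1, 1\] without shifting zero. All-zero columns get scale 1 and map to
#' themselves. One scaler is fitted per cascade level, on that level's
#' expanded training matrix, because expansion products have wildly
#' different ranges.
#'
#' @param x Numeric matrix with finite entries.
#' @return Object of class `"maxabs_scaler"` with the `scale` vector.
#' @export
maxabs_fit <- function(x) {
  x <- as_numeric_matrix(x, "x")
  check_finite(x, "x")
  scale <- apply(abs(x), 2L, max)
  scale[scale == 0] <- 1
  structure(list(scale = unname(scale), n_cols = ncol(x)), class = "maxabs_scaler")
}

#' Apply (or invert) a max-abs scaler
#'
#' @param scaler A [maxabs_fit()] object.
#' @param x Numeric matrix with matching column count.
#' @param invert Multiply by the scale instead of dividing.
#' @return Scaled matrix. Values larger than the fit-time maximum scale
#'   beyond 1; there is no clipping.
#' @export
maxabs_apply <- function(scaler, x, invert = FALSE) {
  stopifnot(inherits(scaler, "maxabs_scaler"))
  x <- as_numeric_matrix(x, "x")
  if (ncol(x) != scaler$n_cols) {
    stop(sprintf("x has %d columns, scaler was fitted on %d", ncol(x), scaler$n_cols),
         call. = FALSE)
  }
  sweep(x, 2L, scaler$scale, if (invert) "*" else "/")
}

#' Seeded train/test split
#'
#' Uniformly shuffles row indices under the seed, then takes the first
#' `ceiling((1 - test_fraction) * N)` rows as the training sample and the
#' remainder as the test sample.
#'
#' @param data A [dataset()].
#' @param test_fraction Fraction held out (default 0.30).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with `train` and `test` datasets.
#' @export
split_train_test <- function(data, test_fraction = 0.30, seed = 1L) {
  stopifnot(inherits(data, "dataset"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(data$x)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  n_train <- as.integer(ceiling((1 - test_fraction) * n))
  list(
    train = dataset_rows(data, perm[seq_len(n_train)]),
    test = dataset_rows(data, perm[(n_train + 1L):n])
  )
}

#' Partition training rows into cascade-level subsamples
#'
#' Splits the training rows into `levels` disjoint blocks of near-equal size
#' (the first `N mod levels` blocks receive one extra row), optionally after
#' a seeded shuffle. Each block trains one level of the cascade.
#'
#' @param n_rows Number of training rows, or a [dataset()].
#' @param levels Number of blocks L (1 <= L <= N).
#' @param seed Integer seed for the shuffle.
#' @param shuffled Shuffle rows before cutting contiguous blocks.
#' @return List of `levels` integer index vectors: pairwise disjoint, jointly
#'   exhaustive, sizes differing by at most 1.
#' @export
partition_levels <- function(n_rows, levels, seed = 1L, shuffled = TRUE) {
  if (inherits(n_rows, "dataset")) n_rows <- nrow(n_rows$x)
  n_rows <- as.integer(n_rows)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  if (levels > n_rows) {
    stop(sprintf("cannot form %d blocks from %d rows", levels, n_rows), call. = FALSE)
  }
  idx <- if (shuffled) with_seed(seed, sample.int(n_rows)) else seq_len(n_rows)
  base <- n_rows %/% levels
  extra <- n_rows %% levels
  sizes <- rep(base, levels) + c(rep(1L, extra), rep(0L, levels - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(levels), function(l) idx[starts[l]:ends[l]])
}
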