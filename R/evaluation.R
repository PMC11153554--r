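#' Regression error metrics
#'
#' The four residual summaries used throughout the package: maximum residual
#' error (MRE, the worst absolute residual), mean absolute error (MAE), mean
#' squared error (MSE) and median absolute error (MedAE; for an even number
#' of residuals, the mean of the two middle values).
#'
#' @param y_true Numeric vector of observed targets.
#' @param y_pred Numeric vector of predictions, same length.
#' @return Object of class `"metric_report"`: list with `mre`, `mae`, `mse`,
#'   `medae` and `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length", call. = FALSE)
  }
  check_finite(y_true, "y_true")
  check_finite(y_pred, "y_pred")
  r <- abs(y_true - y_pred)
  structure(
    list(mre = max(r), mae = mean(r), mse = mean(r^2),
         medae = stats::median(r), n = length(r)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d\n  MRE %.6g | MAE %.6g | MSE %.6g | MedAE %.6g\n",
              x$n, x$mre, x$mae, x$mse, x$medae))
  invisible(x)
}

#' Optimal-complexity cascade depth
#'
#' Implements the optimal-complexity-model criterion: grow the cascade until
#' held-out error stops decreasing. `"argmin"` returns the index of the
#' smallest test error (ties to the smallest index); `"early_stop"` walks the
#' sequence and stops at the first increase, returning the previous level —
#' equivalent on unimodal error sequences.
#'
#' @param test_errors Positive numeric vector of per-level held-out errors,
#'   indexed by cascade depth 1..Lmax.
#' @param mode `"argmin"` (default) or `"early_stop"`.
#' @return Integer: the selected number of levels.
#' @examples
#' select_optimal_levels(c(0.049, 0.008, 0.007, 15.511))  # 3
#' @export
select_optimal_levels <- function(test_errors, mode = c("argmin", "early_stop")) {
  mode <- match.arg(mode)
  test_errors <- as.numeric(test_errors)
  if (length(test_errors) == 0L) stop("empty error sequence", call. = FALSE)
  check_finite(test_errors, "test_errors")
  if (any(test_errors <= 0)) stop("errors must be positive", call. = FALSE)
  if (mode == "argmin") return(which.min(test_errors))
  for (l in seq_along(test_errors)[-1L]) {
    if (test_errors[l] > test_errors[l - 1L]) return(l - 1L)
  }
  length(test_errors)
}

#' Brute-force sweep over the hidden-neuron count
#'
#' Refits the cascade for every candidate number of retained SGTM steps and
#' evaluates it on a holdout sample. Steps are generated in descending
#' importance, so truncating trades noise suppression against capacity; the
#' sweep locates the holdout-error minimum. Grid values exceeding a level's
#' expanded input width are clamped (with a warning) before fitting.
#'
#' @param train,holdout [dataset()]s with targets.
#' @param m_grid Integer vector of candidate hidden-neuron counts (e.g.
#'   `50:230`).
#' @param levels,degree,seed Cascade configuration (see [cascade_fit()]).
#' @param criterion Holdout metric minimised: `"mae"` (default) or `"mse"`.
#' @return List with `table` (data frame: `m`, `mre`, `mae`, `mse`, `medae`)
#'   and `m_star` (the grid value minimising the criterion; ties to the
#'   smaller m).
#' @export
sweep_hidden_neurons <- function(train, holdout, m_grid, levels = 3L, degree = 2L,
                                 seed = 1L, criterion = c("mae", "mse")) {
  criterion <- match.arg(criterion)
  m_grid <- as.integer(m_grid)
  if (length(m_grid) == 0L || any(is.na(m_grid)) || any(m_grid < 1L)) {
    stop("`m_grid` must be a non-empty vector of positive integers", call. = FALSE)
  }
  p <- length(train$feature_names)
  width_cap <- kg_term_count(p + (levels > 1L), degree) + 1L
  if (any(m_grid > width_cap)) {
    warning(sprintf("grid values above the expanded input width were clamped to %d",
                    width_cap))
    m_grid <- unique(pmin(m_grid, width_cap))
  }
  rows <- lapply(m_grid, function(m) {
    fit <- cascade_fit(train, levels = levels, degree = degree,
                       hidden_neurons = m, seed = seed)
    mt <- compute_metrics(holdout$y, predict(fit, holdout$x))
    data.frame(m = m, mre = mt$mre, mae = mt$mae, mse = mt$mse, medae = mt$medae)
  })
  table <- do.call(rbind, rows)
  list(table = table, m_star = table$m[which.min(table[[criterion]])])
}

#' k-fold cross-validation of the cascade
#'
#' Shuffles rows under the seed into `k` near-equal folds; each fold is held
#' out once while the cascade is fitted on the remaining folds. Reports the
#' across-fold mean and sample standard deviation of each error metric.
#'
#' @param data A [dataset()] with a target.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle (also passed to each fit).
#' @param levels,degree,hidden_neurons Cascade configuration.
#' @return Data frame with one row per metric (`mre`, `mae`, `mse`, `medae`)
#'   and columns `mean` and `sd`.
#' @export
kfold_cv <- function(data, k = 5L, seed = 1L, levels = 3L, degree = 2L,
                     hidden_neurons = "full") {
  stopifnot(inherits(data, "dataset"))
  if (is.null(data$y)) stop("`data` must carry a target", call. = FALSE)
  k <- as.integer(k)
  n <- nrow(data$x)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d available rows", k, n), call. = FALSE)
  folds <- partition_levels(n, k, seed = seed, shuffled = TRUE)
  per_fold <- sapply(folds, function(hold) {
    fit <- cascade_fit(dataset_rows(data, setdiff(seq_len(n), hold)),
                       levels = levels, degree = degree,
                       hidden_neurons = hidden_neurons, seed = seed)
    mt <- compute_metrics(data$y[hold], predict(fit, data$x[hold, , drop = FALSE]))
    c(mre = mt$mre, mae = mt$mae, mse = mt$mse, medae = mt$medae)
  })
  data.frame(
    metric = rownames(per_fold),
    mean = rowMeans(per_fold),
    sd = apply(per_fold, 1L, stats::sd),
    row.names = NULL
  )
}
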