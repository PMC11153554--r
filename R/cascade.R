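#' Fit a non-iterative SGTM cascade
#'
#' Trains the cascade ensemble of SGTM neural-like structures. The training
#' rows are partitioned into `levels` disjoint blocks. Level 1 expands its
#' block's features with the Kolmogorov-Gabor polynomial of the configured
#' degree, max-abs-scales the expanded matrix, and fits a supervised SGTM
#' against the block's targets. Every later level first pushes its own
#' block's raw features through the already-trained earlier levels (pure
#' inference, no refitting) to obtain the chained prediction, appends that
#' single value as one extra attribute `y_prev`, and repeats the
#' expand/scale/fit sequence against its block's true targets. At
#' application time the same chain runs level by level; the last level's
#' output is the prediction.
#'
#' Because each level is quadratic in `(x, y_prev)` and `y_prev` is the
#' previous level's response, the composed response surface in the original
#' variables has degree `2^levels` (response surface linearization) while
#' every individual level stays linear in its parameters.
#'
#' @param train A [dataset()] with a target.
#' @param levels Number of cascade levels L (>= 1).
#' @param degree Kolmogorov-Gabor expansion degree per level (default 2;
#'   higher degrees inflate the input width and invite overfitting).
#' @param hidden_neurons Retained SGTM steps per level: an integer shared by
#'   all levels, or `"full"`. Values exceeding a level's capacity are
#'   clamped.
#' @param seed Integer seed driving the partition shuffle.
#' @param shuffled_partition Shuffle rows before blocking (default `TRUE`).
#' @return Object of class `"sgtm_cascade"`: per-level `basis`, `scaler` and
#'   `sgtm` models plus the configuration.
#' @examples
#' gen <- make_polynomial_dataset(400, 2, degree = 2, noise_sd = 0.01, seed = 7)
#' fit <- cascade_fit(gen$data, levels = 2, seed = 7)
#' head(predict(fit, gen$data$x))
#' @seealso [cascade_augment()], [predict.sgtm_cascade()], [compose_polynomial()]
#' @export
cascade_fit <- function(train, levels = 3L, degree = 2L, hidden_neurons = "full",
                        seed = 1L, shuffled_partition = TRUE) {
  stopifnot(inherits(train, "dataset"))
  if (is.null(train$y)) stop("`train` must carry a target", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  if (!identical(hidden_neurons, "full")) {
    hidden_neurons <- as.integer(hidden_neurons)
    if (is.na(hidden_neurons) || hidden_neurons < 1L) {
      stop("`hidden_neurons` must be a positive integer or \"full\"", call. = FALSE)
    }
  }

  blocks <- partition_levels(train, levels, seed = seed, shuffled = shuffled_partition)
  undersized <- which(vapply(blocks, length, 1L) < 2L)
  if (length(undersized) > 0L) {
    stop(sprintf("cascade level %d would train on fewer than 2 rows; reduce `levels`",
                 undersized[1L]), call. = FALSE)
  }

  model <- structure(
    list(
      config = list(levels = levels, degree = as.integer(degree),
                    hidden_neurons = hidden_neurons, seed = as.integer(seed),
                    shuffled_partition = isTRUE(shuffled_partition)),
      feature_names = train$feature_names,
      target_name = train$target_name,
      levels = vector("list", levels)
    ),
    class = "sgtm_cascade"
  )

  for (l in seq_len(levels)) {
    bx <- train$x[blocks[[l]], , drop = FALSE]
    by <- train$y[blocks[[l]]]
    if (l == 1L) {
      vars <- train$feature_names
      input <- bx
    } else {
      vars <- c(train$feature_names, "y_prev")
      y_prev <- cascade_augment(model, bx, upto_level = l - 1L)
      input <- cbind(bx, y_prev)
    }
    basis <- kg_basis(vars, degree)
    expanded <- kg_expand(input, basis)
    scaler <- maxabs_fit(expanded)
    scaled <- maxabs_apply(scaler, expanded)
    m <- if (identical(hidden_neurons, "full")) "full" else
      min(hidden_neurons, ncol(scaled) + 1L)
    model$levels[[l]] <- list(basis = basis, scaler = scaler,
                              sgtm = sgtm_fit(scaled, by, m = m))
  }
  model
}

#' @export
print.sgtm_cascade <- function(x, ...) {
  fitted <- sum(!vapply(x$levels, is.null, TRUE))
  cat(sprintf(
    "<sgtm_cascade> %d level(s), degree %d expansion, hidden_neurons = %s, %d feature(s)\n",
    x$config$levels, x$config$degree, as.character(x$config$hidden_neurons),
    length(x$feature_names)
  ))
  if (fitted > 0L) {
    widths <- vapply(x$levels[seq_len(fitted)],
                     function(l) length(l$scaler$scale), 1L)
    cat(sprintf("  expanded input widths: %s\n", paste(widths, collapse = ", ")))
  }
  invisible(x)
}

#' Chained prediction up to a given cascade level
#'
#' Runs the application-mode chain: for each level in turn, build that
#' level's input (the original features, plus the previous level's
#' prediction when beyond level 1), expand, scale with the level's stored
#' scaler, and predict with the level's SGTM. Only the latest prediction is
#' carried forward — the chain is Markov in the single previous output.
#'
#' @param model A fitted [cascade_fit()] model (levels 1..`upto_level` must
#'   be trained).
#' @param x Numeric feature matrix (original, unexpanded variables).
#' @param upto_level Stop after this level and return its output.
#' @return Numeric vector of level-`upto_level` predictions.
#' @export
cascade_augment <- function(model, x, upto_level) {
  stopifnot(inherits(model, "sgtm_cascade"))
  upto_level <- as.integer(upto_level)
  if (upto_level < 1L || upto_level > model$config$levels) {
    stop(sprintf("`upto_level` must lie in 1..%d", model$config$levels), call. = FALSE)
  }
  x <- as_numeric_matrix(x, "x")
  check_finite(x, "x")
  if (ncol(x) != length(model$feature_names)) {
    stop(sprintf("x has %d columns, model expects %d features",
                 ncol(x), length(model$feature_names)), call. = FALSE)
  }
  y_prev <- NULL
  for (l in seq_len(upto_level)) {
    lvl <- model$levels[[l]]
    if (is.null(lvl)) stop(sprintf("cascade level %d is not fitted", l), call. = FALSE)
    input <- if (l == 1L) x else cbind(x, y_prev)
    scaled <- maxabs_apply(lvl$scaler, kg_expand(input, lvl$basis))
    y_prev <- predict(lvl$sgtm, scaled)
  }
  y_prev
}

#' Predict with a fitted SGTM cascade
#'
#' @param object A fitted [cascade_fit()] model.
#' @param x Numeric feature matrix (original variables).
#' @param ... Unused.
#' @return Numeric vector: the final cascade level's output.
#' @export
predict.sgtm_cascade <- function(object, x, ...) {
  cascade_augment(object, x, upto_level = object$config$levels)
}
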