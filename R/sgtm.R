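#' Fit a non-iterative SGTM neural-like structure
#'
#' The Successive Geometric Transformations Model (SGTM) trains without
#' iterative weight optimisation. At each step it selects the training row
#' with the largest Euclidean norm as a base direction, projects every row
#' onto that (unit-normalised) direction, and subtracts the projection —
#' a pivoted Gram-Schmidt orthogonalisation whose base directions align with
#' the longest axes of the data's scattering ellipsoid, so the per-row
#' projection coefficients are principal-component-like coordinates.
#'
#' In *unsupervised* mode (`y = NULL`) the model is a lossless
#' decomposition: with a full set of steps the training residual is driven
#' to (numerically) zero and [sgtm_reconstruct()] inverts
#' [sgtm_transform()] exactly.
#'
#' In *supervised* mode the rows are augmented with the (centred) target
#' and the same pivoted orthogonalisation is run on the augmented matrix.
#' The exact hidden coefficient of a step uses the full augmented vector,
#' which is unavailable at application time, so each step carries a scalar
#' least-squares correction from the input-only coefficient to the exact
#' one: `alphas` holds the classical per-step formula
#' `sum(k k_in) / sum(k_in^2)`, which is exact when the steps' input parts
#' are mutually orthogonal. Because in general they are not, the
#' corrections actually used for prediction (`gains`) are calibrated
#' jointly, by one least-squares fit of the training outputs on the
#' per-step contribution profiles — the full normal equations whose
#' diagonal approximation is `alphas`. See [predict.sgtm()] for the
#' application mode.
#'
#' Steps are generated in descending order of captured energy; truncating to
#' the first `m` steps (the "number of hidden neurons") discards the
#' smallest, noise-dominated components. In supervised mode `"full"` retains
#' `p` steps: the input space is `p`-dimensional, so at most `p` hidden
#' coefficients are identifiable from the inputs alone at application time;
#' the remaining steps of the augmented orthogonalisation carry only
#' output-residual (noise) energy and degrade prediction. Values up to
#' `p + q` may still be requested explicitly.
#'
#' @param x Numeric matrix (N x p) of inputs.
#' @param y Optional numeric vector or matrix (N x q) of outputs; `NULL` for
#'   unsupervised mode.
#' @param m Number of transformation steps to retain, or `"full"` to iterate
#'   until the residual is numerically exhausted (at most `p` steps
#'   unsupervised and, for the identifiability reason above, also `p`
#'   supervised; explicit values up to `p + q` are accepted).
#' @param center Centre columns by their training means (default `TRUE`).
#'   Centring carries the intercept: means are added back at prediction and
#'   reconstruction time.
#' @param rank_tol Relative tolerance below which a candidate base norm is
#'   considered numerically zero and step creation stops.
#' @return An object of class `"sgtm"`: a list with the step matrix
#'   `directions` (m x (p+q), orthonormal rows), `alphas`, `base_row_indices`,
#'   `base_norms`, centring means and the dimensions `p`, `q`, `m`.
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' fit <- sgtm_fit(X)                 # unsupervised decomposition
#' max(abs(sgtm_reconstruct(fit, sgtm_transform(fit, X)) - X))
#' y <- X[, 1] - 2 * X[, 2] + rnorm(20, sd = 0.01)
#' mod <- sgtm_fit(X, y)
#' head(predict(mod, X))
#' @seealso [sgtm_transform()], [sgtm_reconstruct()], [predict.sgtm()]
#' @export
sgtm_fit <- function(x, y = NULL, m = "full", center = TRUE, rank_tol = 1e-10) {
  x <- as_numeric_matrix(x, "x")
  check_finite(x, "x")
  n <- nrow(x)
  p <- ncol(x)
  supervised <- !is.null(y)
  if (supervised) {
    y <- as_numeric_matrix(y, "y")
    check_finite(y, "y")
    if (nrow(y) != n) stop("x and y must have the same number of rows", call. = FALSE)
    if (n < 2L) stop("supervised fitting needs at least 2 rows", call. = FALSE)
  }
  q <- if (supervised) ncol(y) else 0L
  d <- p + q

  max_steps <- if (supervised) p else d
  if (!identical(m, "full")) {
    m <- as.integer(m)
    if (is.na(m) || m < 0L) stop("`m` must be a non-negative integer or \"full\"", call. = FALSE)
    if (m > d) stop(sprintf("`m` (%d) cannot exceed p + q = %d", m, d), call. = FALSE)
    max_steps <- m
  }

  input_means <- if (center) colMeans(x) else numeric(p)
  output_means <- if (supervised && center) colMeans(y) else numeric(q)
  r <- sweep(x, 2L, input_means)
  if (supervised) {
    x_centred0 <- r
    y_centred0 <- sweep(y, 2L, output_means)
    r <- cbind(r, y_centred0)
  }

  init_row_norms <- sqrt(rowSums(r * r))
  norm_floor <- rank_tol * max(init_row_norms, 0)
  init_frob <- sqrt(sum(r * r))

  directions <- matrix(0, nrow = max_steps, ncol = d)
  alphas <- numeric(max_steps)
  base_row_indices <- integer(max_steps)
  base_norms <- numeric(max_steps)

  s <- 0L
  while (s < max_steps) {
    norms2 <- rowSums(r * r)
    i <- which.max(norms2) # ties resolved to the smallest row index
    bn <- sqrt(norms2[i])
    if (bn <= norm_floor) break
    if (identical(m, "full") && sqrt(sum(norms2)) <= rank_tol * init_frob) break
    b <- r[i, ] / bn
    k <- drop(r %*% b)
    s <- s + 1L
    directions[s, ] <- b
    base_row_indices[s] <- i
    base_norms[s] <- bn
    if (supervised) {
      b_in <- b[seq_len(p)]
      k_in <- drop(r[, seq_len(p), drop = FALSE] %*% b_in)
      denom <- sum(k_in * k_in)
      alphas[s] <- if (denom <= 1e-30) 0 else sum(k * k_in) / denom
    }
    r <- r - tcrossprod(k, b)
  }

  model <- structure(
    list(
      directions = directions[seq_len(s), , drop = FALSE],
      alphas = alphas[seq_len(s)],
      base_row_indices = base_row_indices[seq_len(s)],
      base_norms = base_norms[seq_len(s)],
      input_means = input_means,
      output_means = output_means,
      p = p, q = q, m = s,
      supervised = supervised,
      rank_tol = rank_tol
    ),
    class = "sgtm"
  )
  if (supervised) {
    cal <- calibrate_readout(model, x_centred0, y_centred0)
    model$gains <- cal$gains
    model$app_weights <- cal$app_weights
  }
  model
}

# Calibrate the application-mode readout. Each retained step contributes
# ktilde_S * b_out_S to the prediction, where ktilde_S = gain_S * k_in_S
# corrects the input-only hidden coefficient k_in_S = x_centred . b_in_S.
# The per-step least-squares formula behind `alphas` is exact only when the
# steps' input parts are mutually orthogonal; in general they are not, so
# the gains are calibrated jointly: one least-squares solve of the training
# outputs on the per-step contribution profiles (the joint normal equations
# whose diagonal approximation is `alphas`). Steps with a zero output part
# have an identically zero profile and keep gain 0 — they contribute
# nothing at application time. The collapsed affine readout is cached as
# `app_weights`.
calibrate_readout <- function(model, x_centred, y_centred) {
  p <- model$p
  q <- model$q
  m <- model$m
  if (m == 0L) return(list(gains = numeric(0), app_weights = matrix(0, p, q)))
  b_in <- model$directions[, seq_len(p), drop = FALSE]
  b_out <- model$directions[, p + seq_len(q), drop = FALSE]
  h <- x_centred %*% t(b_in) # N x m input-only hidden coefficients
  # regressor s: contribution profile h[, s] (x) b_out[s, ], flattened over outputs
  reg <- matrix(0, nrow(h) * q, m)
  for (s in seq_len(m)) reg[, s] <- as.vector(tcrossprod(h[, s], b_out[s, ]))
  gains <- stats::lm.fit(reg, as.vector(y_centred))$coefficients
  gains[is.na(gains)] <- 0
  list(gains = unname(gains),
       app_weights = t(b_in) %*% (gains * b_out))
}

#' @export
print.sgtm <- function(x, ...) {
  cat(sprintf(
    "<sgtm> %s, p = %d%s, %d step(s) retained\n",
    if (x$supervised) "supervised" else "unsupervised",
    x$p, if (x$q > 0L) sprintf(", q = %d", x$q) else "", x$m
  ))
  invisible(x)
}

check_sgtm_input <- function(model, x, p) {
  x <- as_numeric_matrix(x, "x")
  check_finite(x, "x")
  if (ncol(x) != p) {
    stop(sprintf("input has %d columns, model expects %d", ncol(x), p), call. = FALSE)
  }
  x
}

#' Hidden-layer coordinates of an SGTM model
#'
#' Maps rows of `x` to their projection coefficients on the model's base
#' directions — the hidden-layer signals of the neural-like structure.
#' Centring by the training means is applied first; coefficients are computed
#' step by step, peeling each projection off the running residual.
#'
#' @param model A fitted unsupervised [sgtm_fit()] model.
#' @param x Numeric matrix with `model$p` columns.
#' @return Numeric matrix (nrow(x) x m) of coefficients, one column per step.
#' @export
sgtm_transform <- function(model, x) {
  stopifnot(inherits(model, "sgtm"))
  if (model$q != 0L) stop("sgtm_transform() applies to unsupervised models", call. = FALSE)
  x <- check_sgtm_input(model, x, model$p)
  r <- sweep(x, 2L, model$input_means)
  k <- matrix(0, nrow = nrow(x), ncol = model$m)
  for (s in seq_len(model$m)) {
    b <- model$directions[s, ]
    k[, s] <- drop(r %*% b)
    r <- r - tcrossprod(k[, s], b)
  }
  k
}

#' Inverse transformation from hidden-layer coordinates
#'
#' Rebuilds input vectors from their projection coefficients:
#' `x_hat = means + sum_S K[, S] * direction_S`. With a full set of steps this
#' inverts [sgtm_transform()] exactly on the training matrix.
#'
#' @param model A fitted unsupervised [sgtm_fit()] model.
#' @param k Coefficient matrix with `model$m` columns.
#' @return Numeric matrix (nrow(k) x p).
#' @export
sgtm_reconstruct <- function(model, k) {
  stopifnot(inherits(model, "sgtm"))
  if (model$q != 0L) stop("sgtm_reconstruct() applies to unsupervised models", call. = FALSE)
  k <- as_numeric_matrix(k, "k")
  if (ncol(k) != model$m) {
    stop(sprintf("k has %d columns, model has %d steps", ncol(k), model$m), call. = FALSE)
  }
  sweep(k %*% model$directions[, seq_len(model$p), drop = FALSE],
        2L, model$input_means, "+")
}

#' Predict outputs with a supervised SGTM model
#'
#' Application mode. Each input row is centred and projected onto the input
#' part of every retained base direction, giving the input-only hidden
#' coefficients; each coefficient is corrected by its step's calibrated
#' gain (the jointly-fitted least-squares analogue of the per-step `alpha`,
#' see [sgtm_fit()]) and the corrected coefficient's contribution along the
#' output part of its direction is accumulated. The whole map is affine and
#' is cached at fit time as `app_weights`; this function applies it. Output
#' means are added back at the end.
#'
#' @param object A supervised [sgtm_fit()] model.
#' @param x Numeric matrix with `object$p` columns.
#' @param ... Unused.
#' @return Numeric vector of predictions (or matrix when q > 1).
#' @export
predict.sgtm <- function(object, x, ...) {
  if (object$q < 1L) stop("model was fitted unsupervised; nothing to predict", call. = FALSE)
  x <- check_sgtm_input(object, x, object$p)
  yhat <- sweep(x, 2L, object$input_means) %*% object$app_weights
  yhat <- sweep(yhat, 2L, object$output_means, "+")
  if (object$q == 1L) drop(yhat) else yhat
}
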