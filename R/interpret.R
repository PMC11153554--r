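#' Construct a sparse multivariate polynomial
#'
#' Polynomials are stored as a sparse mapping from exponent vectors to real
#' coefficients over named variables. Duplicate exponent rows are summed;
#' the zero exponent vector (the intercept) is always kept, with coefficient
#' 0 when absent.
#'
#' @param variable_names Ordered character vector of variable names.
#' @param exponents Integer matrix, one row per term, one column per
#'   variable (non-negative entries).
#' @param coefficients Numeric vector, one per exponent row.
#' @return Object of class `"polynomial"`.
#' @export
polynomial <- function(variable_names, exponents, coefficients) {
  if (!is.character(variable_names) || anyDuplicated(variable_names)) {
    stop("`variable_names` must be unique character names", call. = FALSE)
  }
  n <- length(variable_names)
  if (length(coefficients) == 0L) {
    exponents <- matrix(0L, nrow = 0L, ncol = n)
  }
  exponents <- as.matrix(exponents)
  storage.mode(exponents) <- "integer"
  if (ncol(exponents) != n || nrow(exponents) != length(coefficients)) {
    stop("`exponents` must be (#terms x #variables) matching `coefficients`",
         call. = FALSE)
  }
  if (any(exponents < 0L)) stop("exponents must be non-negative", call. = FALSE)
  # aggregate duplicated exponent vectors and guarantee an intercept row
  exponents <- rbind(matrix(0L, 1L, n), exponents)
  coefficients <- c(0, as.numeric(coefficients))
  key <- apply(exponents, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  agg <- tapply(coefficients, key, sum)
  exponents <- exponents[first, , drop = FALSE]
  coefficients <- as.numeric(agg[key[first]])
  deg <- rowSums(exponents)
  ord <- do.call(order, c(list(deg),
                          lapply(seq_len(n), function(j) -exponents[, j])))
  structure(
    list(variable_names = variable_names,
         exponents = exponents[ord, , drop = FALSE],
         coefficients = coefficients[ord]),
    class = "polynomial"
  )
}

#' Evaluate a polynomial
#'
#' Direct monomial-sum evaluation.
#'
#' @param p A [polynomial()].
#' @param x Numeric vector (one point) or matrix (rows = points) whose
#'   length/column count equals the number of variables.
#' @return Numeric scalar or vector of values.
#' @export
poly_eval <- function(p, x) {
  stopifnot(inherits(p, "polynomial"))
  scalar <- is.vector(x) && is.numeric(x)
  if (scalar) x <- matrix(x, nrow = 1L) # one point
  x <- as_numeric_matrix(x, "x")
  if (ncol(x) != length(p$variable_names)) {
    stop(sprintf("point has %d coordinates, polynomial has %d variables",
                 ncol(x), length(p$variable_names)), call. = FALSE)
  }
  out <- numeric(nrow(x))
  for (t in seq_along(p$coefficients)) {
    e <- p$exponents[t, ]
    mono <- rep(1, nrow(x))
    for (v in which(e > 0L)) mono <- mono * x[, v]^e[v]
    out <- out + p$coefficients[t] * mono
  }
  if (scalar && length(out) == 1L) out[[1L]] else out
}

#' Total degree of a polynomial
#'
#' Maximum total degree over terms whose coefficient magnitude exceeds
#' `tol`; the zero polynomial has degree 0.
#'
#' @param p A [polynomial()].
#' @param tol Coefficients at or below this magnitude are ignored.
#' @return Integer degree.
#' @export
poly_degree <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "polynomial"))
  live <- abs(p$coefficients) > tol
  if (!any(live)) return(0L)
  as.integer(max(rowSums(p$exponents[live, , drop = FALSE])))
}

poly_constant <- function(variable_names, value) {
  polynomial(variable_names, matrix(0L, 1L, length(variable_names)), value)
}

poly_add <- function(a, b) {
  stopifnot(identical(a$variable_names, b$variable_names))
  polynomial(a$variable_names, rbind(a$exponents, b$exponents),
             c(a$coefficients, b$coefficients))
}

poly_mul <- function(a, b) {
  stopifnot(identical(a$variable_names, b$variable_names))
  na <- nrow(a$exponents); nb <- nrow(b$exponents)
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  polynomial(a$variable_names,
             a$exponents[ia, , drop = FALSE] + b$exponents[ib, , drop = FALSE],
             a$coefficients[ia] * b$coefficients[ib])
}

poly_pow <- function(a, k) {
  out <- poly_constant(a$variable_names, 1)
  for (i in seq_len(k)) out <- poly_mul(out, a)
  out
}

# Drop terms with |coefficient| <= tol (the intercept row is always kept).
poly_prune <- function(p, tol = 1e-12) {
  keep <- abs(p$coefficients) > tol | rowSums(p$exponents) == 0L
  polynomial(p$variable_names, p$exponents[keep, , drop = FALSE],
             p$coefficients[keep])
}

#' Substitute a polynomial for one variable of another
#'
#' Exact symbolic substitution with full expansion: every occurrence of
#' `var` in `p` is replaced by the polynomial `value`, whose variables must
#' be exactly `p`'s remaining variables.
#'
#' @param p A [polynomial()] containing variable `var`.
#' @param var Name of the variable to eliminate.
#' @param value A [polynomial()] over the remaining variables.
#' @return A [polynomial()] over the remaining variables.
#' @export
poly_substitute <- function(p, var, value) {
  stopifnot(inherits(p, "polynomial"), inherits(value, "polynomial"))
  vi <- match(var, p$variable_names)
  if (is.na(vi)) stop(sprintf("'%s' is not a variable of `p`", var), call. = FALSE)
  rest <- p$variable_names[-vi]
  if (!identical(value$variable_names, rest)) {
    stop("`value` must be a polynomial over exactly the remaining variables",
         call. = FALSE)
  }
  out <- poly_constant(rest, 0)
  # cache powers of `value`
  max_pow <- max(p$exponents[, vi], 0L)
  pows <- vector("list", max_pow + 1L)
  pows[[1L]] <- poly_constant(rest, 1)
  for (k in seq_len(max_pow)) pows[[k + 1L]] <- poly_mul(pows[[k]], value)
  for (t in seq_along(p$coefficients)) {
    e <- p$exponents[t, ]
    term <- polynomial(rest, matrix(e[-vi], 1L), p$coefficients[t])
    out <- poly_add(out, poly_mul(term, pows[[e[vi] + 1L]]))
  }
  out
}

#' @export
format.polynomial <- function(x, digits = 6L, tol = 1e-12, ...) {
  live <- abs(x$coefficients) > tol
  if (!any(live)) return("0")
  terms <- character(0L)
  for (t in which(live)) {
    e <- x$exponents[t, ]
    on <- which(e > 0L)
    mono <- paste(ifelse(e[on] == 1L, x$variable_names[on],
                         paste0(x$variable_names[on], "^", e[on])),
                  collapse = "*")
    cf <- signif(x$coefficients[t], digits)
    terms <- c(terms, if (mono == "") format(cf) else paste0(format(cf), "*", mono))
  }
  gsub("+ -", "- ", paste(terms, collapse = " + "), fixed = TRUE)
}

#' @export
print.polynomial <- function(x, ...) {
  cat(sprintf("<polynomial> %d variable(s), degree %d\n",
              length(x$variable_names), poly_degree(x)))
  cat(" ", format(x, ...), "\n")
  invisible(x)
}

#' Coefficient table of a polynomial
#'
#' @param p A [polynomial()].
#' @param tol Terms with smaller coefficient magnitude are dropped
#'   (the intercept row is always kept).
#' @return A data frame with one exponent column per variable plus a
#'   `coefficient` column, suitable for CSV export.
#' @export
poly_to_table <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "polynomial"))
  p <- poly_prune(p, tol)
  out <- as.data.frame(p$exponents)
  names(out) <- p$variable_names
  out$coefficient <- p$coefficients
  out
}

#' Identify an affine map by diagonal test signals
#'
#' Probes a black-box predictor that is affine in its input with the zero
#' vector and the unit vectors (the rows of a diagonal test-signal matrix)
#' to read off its intercept and weights. Affineness is verified by checking
#' `f(e_j + e_k) = intercept + w_j + w_k` on five deterministic index pairs.
#'
#' @param predictor Function mapping a numeric matrix (rows = points in the
#'   d-dimensional input space) to a numeric vector of outputs.
#' @param d Input dimensionality.
#' @param tol Relative tolerance for the affineness check.
#' @return List with `intercept` (scalar) and `weights` (length-d vector).
#' @export
extract_affine <- function(predictor, d, tol = 1e-8) {
  d <- as.integer(d)
  stopifnot(is.function(predictor), d >= 1L)
  probes <- rbind(rep(0, d), diag(d))
  vals <- as.numeric(predictor(probes))
  if (length(vals) != d + 1L) {
    stop("`predictor` must return one value per input row", call. = FALSE)
  }
  intercept <- vals[1L]
  weights <- vals[-1L] - intercept
  # superposition probes e_j + e_k and scaling probes 2 e_j
  singles <- with_seed(971L, sample.int(d, min(d, 3L)))
  pr2 <- matrix(0, length(singles), d)
  for (i in seq_along(singles)) pr2[i, singles[i]] <- 2
  got <- as.numeric(predictor(pr2))
  want <- intercept + 2 * weights[singles]
  if (d >= 2L) {
    pairs <- with_seed(972L, replicate(5L, sort(sample.int(d, 2L))))
    pr <- matrix(0, 5L, d)
    for (i in 1:5) pr[i, pairs[, i]] <- 1
    got <- c(got, as.numeric(predictor(pr)))
    want <- c(want, intercept + weights[pairs[1L, ]] + weights[pairs[2L, ]])
  }
  if (any(abs(got - want) > tol * pmax(1, abs(want)))) {
    stop("predictor failed the affineness check; it is not affine in its input",
         call. = FALSE)
  }
  list(intercept = intercept, weights = weights)
}

#' Per-level polynomial of a fitted cascade
#'
#' Expresses one cascade level's raw prediction map as an explicit
#' polynomial of the configured expansion degree in the level's raw
#' variables (the original features, plus `y_prev` beyond level 1). The
#' level's SGTM is affine in its scaled expanded features, so its intercept
#' and weights are identified by diagonal test-signal probing
#' ([extract_affine()]); the max-abs scaling and the centring are affine too
#' and are folded in symbolically, so the emitted coefficients refer to the
#' raw, unscaled variables.
#'
#' @param model A fitted [cascade_fit()] model.
#' @param level Level index (1..L).
#' @return A [polynomial()] over `c(feature_names, "y_prev"[level > 1])`
#'   whose evaluation equals the level's prediction map.
#' @export
level_polynomial <- function(model, level) {
  stopifnot(inherits(model, "sgtm_cascade"))
  level <- as.integer(level)
  lvl <- model$levels[[level]]
  if (is.null(lvl)) stop(sprintf("cascade level %d is not fitted", level), call. = FALSE)
  scale <- lvl$scaler$scale
  f <- function(e_raw) predict(lvl$sgtm, sweep(e_raw, 2L, scale, "/"))
  aff <- extract_affine(f, d = length(scale))
  poly_add(
    poly_constant(lvl$basis$variable_names, aff$intercept),
    polynomial(lvl$basis$variable_names, lvl$basis$exponents, aff$weights)
  )
}

#' Compose a fitted cascade into a single polynomial
#'
#' Substitutes each level's polynomial for the chained variable `y_prev` of
#' the next level, with exact symbolic expansion, yielding one polynomial in
#' the original input variables that reproduces [predict.sgtm_cascade()].
#' With quadratic levels the composed degree doubles per level, reaching
#' `2^L` for generic coefficients. The term count explodes combinatorially
#' with the number of features, so composition is refused above
#' `max_features` (use the neural form instead).
#'
#' @param model A fitted [cascade_fit()] model.
#' @param max_features Refuse composition when the model has more input
#'   features than this (default 6).
#' @param drop_tol Terms with smaller coefficient magnitude are pruned
#'   after each substitution.
#' @return A [polynomial()] over the model's original feature names.
#' @export
compose_polynomial <- function(model, max_features = 6L, drop_tol = 1e-12) {
  stopifnot(inherits(model, "sgtm_cascade"))
  p <- length(model$feature_names)
  if (p > max_features) {
    stop(sprintf(paste0(
      "composition with %d features would be combinatorially huge; ",
      "raise `max_features` or use the neural form (predict())"), p), call. = FALSE)
  }
  out <- level_polynomial(model, 1L)
  for (l in seq_len(model$config$levels)[-1L]) {
    out <- poly_prune(poly_substitute(level_polynomial(model, l), "y_prev", out),
                      drop_tol)
  }
  out
}
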