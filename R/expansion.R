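#' Number of Kolmogorov-Gabor polynomial terms
#'
#' Counts the monomials of total degree 1..`degree` in `n` variables (the
#' constant term is excluded; intercepts are carried by column centring
#' elsewhere in the pipeline): `choose(n + degree, degree) - 1`. For the
#' default quadratic expansion this is `n + n(n+1)/2`.
#'
#' @param n Number of variables (>= 1).
#' @param degree Polynomial degree (>= 1).
#' @return Integer term count.
#' @examples
#' kg_term_count(2, 2)   # 5
#' kg_term_count(18, 2)  # 189
#' @export
kg_term_count <- function(n, degree) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      !is.numeric(degree) || length(degree) != 1L || is.na(degree) || degree < 1) {
    stop("`n` and `degree` must be positive integers", call. = FALSE)
  }
  as.integer(round(choose(n + degree, degree))) - 1L
}

# All exponent vectors of total degree `d` over `n` variables, as rows in
# descending lexicographic order (first variable's exponent decreasing).
exponents_of_degree <- function(d, n) {
  if (n == 1L) return(matrix(d, nrow = 1L))
  out <- vector("list", d + 1L)
  for (first in d:0) {
    rest <- exponents_of_degree(d - first, n - 1L)
    out[[d - first + 1L]] <- cbind(first, rest, deparse.level = 0L)
  }
  do.call(rbind, out)
}

#' Canonical Kolmogorov-Gabor monomial basis
#'
#' Builds the ordered monomial basis of all terms of total degree 1..`degree`
#' over the named variables. The ordering is frozen so serialised models are
#' portable: ascending total degree, then descending lexicographic on the
#' exponent vectors. The first `n` terms are therefore the original variables
#' in order.
#'
#' @param variable_names Character vector of unique variable names.
#' @param degree Maximum total degree (>= 1); quadratic by default in the
#'   rest of the pipeline.
#' @return Object of class `"kg_basis"`: list with `variable_names`,
#'   `degree` and the integer exponent matrix `exponents` (terms x n).
#' @examples
#' b <- kg_basis(c("x1", "x2"), 2)
#' kg_basis_labels(b)  # "x1" "x2" "x1^2" "x1*x2" "x2^2"
#' @export
kg_basis <- function(variable_names, degree = 2L) {
  if (!is.character(variable_names) || length(variable_names) == 0L) {
    stop("`variable_names` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(variable_names)) {
    stop("`variable_names` must be unique", call. = FALSE)
  }
  n <- length(variable_names)
  n_terms <- kg_term_count(n, degree)
  expo <- do.call(rbind, lapply(seq_len(degree), exponents_of_degree, n = n))
  storage.mode(expo) <- "integer"
  dimnames(expo) <- NULL
  stopifnot(nrow(expo) == n_terms)
  structure(
    list(variable_names = variable_names, degree = as.integer(degree),
         exponents = expo),
    class = "kg_basis"
  )
}

#' Human-readable labels for basis monomials
#'
#' @param basis A [kg_basis()].
#' @return Character vector, one label per term (e.g. `"x1^2"`, `"x1*x2"`).
#' @export
kg_basis_labels <- function(basis) {
  stopifnot(inherits(basis, "kg_basis"))
  apply(basis$exponents, 1L, function(e) {
    on <- which(e > 0L)
    paste(ifelse(e[on] == 1L, basis$variable_names[on],
                 paste0(basis$variable_names[on], "^", e[on])),
          collapse = "*")
  })
}

#' Expand a matrix into Kolmogorov-Gabor polynomial features
#'
#' Column `j` of the result is the product of input columns raised to the
#' exponents of term `j` of the canonical basis; the first `n` columns equal
#' the input. This nonlinear input extension is what lets a linear-in-
#' parameters SGTM level fit a quadratic response surface.
#'
#' @param x Numeric matrix (M x n) with finite entries.
#' @param degree Maximum total degree, or a pre-built [kg_basis()] whose
#'   variable count matches `ncol(x)`.
#' @return Numeric matrix (M x `kg_term_count(n, degree)`), columns named by
#'   [kg_basis_labels()].
#' @examples
#' kg_expand(matrix(c(2, 3), 1), 2)  # 2 3 4 6 9
#' @export
kg_expand <- function(x, degree = 2L) {
  x <- as_numeric_matrix(x, "x")
  check_finite(x, "x")
  basis <- if (inherits(degree, "kg_basis")) degree else {
    nms <- colnames(x)
    if (is.null(nms)) nms <- paste0("x", seq_len(ncol(x)))
    kg_basis(nms, degree)
  }
  if (ncol(x) != length(basis$variable_names)) {
    stop("column count of `x` does not match the basis", call. = FALSE)
  }
  out <- matrix(1, nrow = nrow(x), ncol = nrow(basis$exponents))
  for (j in seq_len(nrow(basis$exponents))) {
    e <- basis$exponents[j, ]
    for (v in which(e > 0L)) {
      out[, j] <- out[, j] * x[, v]^e[v]
    }
  }
  colnames(out) <- kg_basis_labels(basis)
  out
}
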