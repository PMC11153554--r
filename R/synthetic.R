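#' Generate a polynomial response surface of known degree
#'
#' Draws features i.i.d. uniform on \[-1, 1\] and a target that is an exact
#' polynomial of the requested total degree — seeded coefficients on *all*
#' monomials up to `degree`, intercept included — plus optional Gaussian
#' noise. Returning the generating polynomial alongside the data enables
#' parameter-recovery tests: a model whose function class contains the
#' surface should drive held-out error to numerical zero when `noise_sd`
#' is 0.
#'
#' @param n_samples Number of rows (>= 2).
#' @param n_features Number of features.
#' @param degree Total degree of the generating polynomial.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed; the same seed yields a bit-identical dataset.
#' @param coefficient_scale Coefficients are uniform on
#'   \[-`coefficient_scale`, `coefficient_scale`\].
#' @return List with `data` (a [dataset()]) and `true_polynomial`
#'   (a [polynomial()]).
#' @export
make_polynomial_dataset <- function(n_samples, n_features = 2L, degree = 2L,
                                    noise_sd = 0, seed = 1L,
                                    coefficient_scale = 1) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("`n_samples` must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  vars <- paste0("x", seq_len(n_features))
  basis <- kg_basis(vars, degree)
  with_seed(seed, {
    coefs <- stats::runif(nrow(basis$exponents) + 1L, -1, 1) * coefficient_scale
    true_poly <- poly_add(poly_constant(vars, coefs[1L]),
                          polynomial(vars, basis$exponents, coefs[-1L]))
    x <- matrix(stats::runif(n_samples * n_features, -1, 1), n_samples, n_features,
                dimnames = list(NULL, vars))
    y <- poly_eval(true_poly, x)
    if (noise_sd > 0) y <- y + stats::rnorm(n_samples, sd = noise_sd)
    list(data = dataset(x, y, feature_names = vars, target_name = "y"),
         true_polynomial = true_poly)
  })
}

#' Generate a heart-rate-like tabular benchmark
#'
#' Emulates the *shape* of a wearable-sensor stress/heart-rate table — 18
#' correlated numeric predictors and a positive, bounded, smoothly nonlinear
#' target — not its physiological semantics. Features are drawn from a
#' seeded multivariate normal with a random covariance of condition number
#' about 100, then max-abs-bounded into \[-1, 1\] so the quadratic
#' expansion stays numerically tame. The target is
#' `72 + 18 * tanh(smooth nonlinear signal)` beats-per-minute plus
#' heteroscedastic Gaussian noise whose spread grows with the signal.
#'
#' @param n_samples Number of rows (>= 10).
#' @param seed Integer seed.
#' @return A [dataset()] with features `feature_01..feature_18` and target
#'   `heart_rate`.
#' @export
make_healthcare_like <- function(n_samples, seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 10L) stop("`n_samples` must be >= 10", call. = FALSE)
  p <- 18L
  vars <- sprintf("feature_%02d", seq_len(p))
  with_seed(seed, {
    # random correlation structure with controlled conditioning
    q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
    ev <- exp(seq(log(1), log(1e-2), length.out = p))  # condition number 100
    chol_sigma <- t(q %*% (sqrt(ev) * t(q)))
    z <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% chol_sigma
    x <- sweep(z, 2L, pmax(apply(abs(z), 2L, max), .Machine$double.eps), "/")
    colnames(x) <- vars
    w1 <- stats::runif(p, -1, 1)
    w2 <- stats::runif(p, -1, 1)
    signal <- drop(x %*% w1) + sin(pi * x[, 1L] * x[, 2L]) +
      0.8 * x[, 3L]^2 - 0.6 * x[, 4L] * drop(x %*% w2) / sqrt(p)
    hr <- 72 + 18 * tanh(signal)
    noise_sd <- 0.4 + 0.8 * stats::plogis(signal)
    hr <- hr + stats::rnorm(n_samples, sd = noise_sd)
    dataset(x, hr, feature_names = vars, target_name = "heart_rate")
  })
}
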