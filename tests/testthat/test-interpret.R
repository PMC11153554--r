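test_that("polynomial construction canonicalises terms and evaluates exactly", {
  p <- polynomial(c("x1"), matrix(c(2L, 0L), 2, 1), c(1, 2)) # x1^2 + 2
  expect_equal(poly_eval(p, 3), 11)
  expect_equal(poly_degree(p), 2L)
  z <- polynomial(c("a", "b"), matrix(0L, 1, 2), 0)
  expect_equal(poly_degree(z), 0L)
  expect_equal(poly_eval(z, c(5, 5)), 0)
  # duplicate exponent rows are aggregated
  dup <- polynomial("t", matrix(c(1L, 1L), 2, 1), c(2, 3))
  expect_equal(poly_eval(dup, 10), 50)
  # brute-force term-by-term oracle on a random polynomial
  set.seed(61)
  expo <- matrix(sample(0:3, 30, replace = TRUE), 10, 3)
  cf <- rnorm(10)
  p3 <- polynomial(c("u", "v", "w"), expo, cf)
  for (i in 1:5) {
    x <- runif(3, -2, 2)
    manual <- sum(cf * apply(expo, 1, function(e) prod(x^e)))
    expect_equal(poly_eval(p3, x), manual, tolerance = 1e-12)
  }
  expect_error(poly_eval(p3, c(1, 2)), "variables")
})

test_that("diagonal test-signal probing identifies affine maps", {
  f <- function(z) 1 + 2 * z[, 1] - z[, 2]
  aff <- extract_affine(f, 2)
  expect_equal(aff$intercept, 1)
  expect_equal(aff$weights, c(2, -1))
  zero <- extract_affine(function(z) rep(0, nrow(z)), 4)
  expect_equal(zero$intercept, 0)
  expect_equal(zero$weights, rep(0, 4))
  expect_error(extract_affine(function(z) z[, 1]^2, 3), "not affine")
})

test_that("probing a fitted level reproduces its prediction map", {
  gen <- make_polynomial_dataset(300, 2, degree = 3, noise_sd = 0.05, seed = 63)
  fit <- cascade_fit(gen$data, levels = 1, seed = 63)
  lvl <- fit$levels[[1]]
  f <- function(z) predict(lvl$sgtm, sweep(z, 2, lvl$scaler$scale, "/"))
  aff <- extract_affine(f, 5)
  set.seed(64)
  e <- kg_expand(matrix(runif(200, -1, 1), 100, 2), lvl$basis)
  expect_equal(drop(aff$intercept + e %*% aff$weights), f(e), tolerance = 1e-9)
})

test_that("per-level polynomials have the quadratic term structure in raw variables", {
  gen <- make_polynomial_dataset(400, 2, degree = 3, noise_sd = 0.05, seed = 65)
  fit <- cascade_fit(gen$data, levels = 2, seed = 65)
  p1 <- level_polynomial(fit, 1)
  expect_identical(p1$variable_names, c("x1", "x2"))
  expect_identical(nrow(poly_to_table(p1, tol = -1)), 6L)  # intercept + 5 monomials
  expect_equal(poly_degree(p1), 2L)
  p2 <- level_polynomial(fit, 2)
  expect_identical(p2$variable_names, c("x1", "x2", "y_prev"))
  expect_identical(nrow(poly_to_table(p2, tol = -1)), 10L) # intercept + 9 monomials
  # evaluation equivalence against the raw level maps
  x <- matrix(runif(100, -1, 1), 50, 2)
  expect_equal(poly_eval(p1, x), cascade_augment(fit, x, 1), tolerance = 1e-9)
  y1 <- cascade_augment(fit, x, 1)
  expect_equal(poly_eval(p2, cbind(x, y1)), cascade_augment(fit, x, 2),
               tolerance = 1e-9)
})

test_that("symbolic composition doubles the degree at every level", {
  gen <- make_polynomial_dataset(500, 2, degree = 3, noise_sd = 0.05, seed = 67)
  for (L in 1:3) {
    fit <- cascade_fit(gen$data, levels = L, seed = 67)
    expect_identical(poly_degree(compose_polynomial(fit)), as.integer(2^L))
  }
})

test_that("the composed polynomial reproduces the neural chain pointwise", {
  gen <- make_polynomial_dataset(500, 2, degree = 3, noise_sd = 0.05, seed = 69)
  fit <- cascade_fit(gen$data, levels = 3, seed = 69)
  poly <- compose_polynomial(fit)
  expect_identical(poly$variable_names, c("x1", "x2"))
  set.seed(70)
  x <- matrix(runif(2000, -1, 1), 1000, 2)
  neural <- predict(fit, x)
  symbolic <- poly_eval(poly, x)
  expect_lt(max(abs(neural - symbolic) / (1 + abs(neural))), 1e-8)
})

test_that("substitution is exact: composing then evaluating equals chaining", {
  gen <- make_polynomial_dataset(400, 3, degree = 2, noise_sd = 0.05, seed = 71)
  fit <- cascade_fit(gen$data, levels = 2, seed = 71)
  p2 <- level_polynomial(fit, 2)
  p1 <- level_polynomial(fit, 1)
  composed <- poly_substitute(p2, "y_prev", p1)
  set.seed(72)
  x <- matrix(runif(60, -1, 1), 20, 3)
  expect_equal(poly_eval(composed, x),
               poly_eval(p2, cbind(x, poly_eval(p1, x))), tolerance = 1e-10)
})

test_that("composition refuses combinatorially large feature counts", {
  gen <- make_polynomial_dataset(300, 7, degree = 2, noise_sd = 0.05, seed = 73)
  fit <- cascade_fit(gen$data, levels = 2, seed = 73)
  expect_error(compose_polynomial(fit), "max_features|combinatorially")
  expect_s3_class(compose_polynomial(fit, max_features = 7), "polynomial")
})

test_that("coefficient tables round-trip the polynomial terms", {
  p <- polynomial(c("x1", "x2"), rbind(c(1L, 0L), c(0L, 2L), c(1L, 1L)),
                  c(0.5, -2, 1e-15))
  tab <- poly_to_table(p)
  expect_identical(names(tab), c("x1", "x2", "coefficient"))
  expect_identical(nrow(tab), 3L) # intercept kept, tiny cross term dropped
  expect_equal(sort(tab$coefficient), sort(c(0, 0.5, -2)))
})
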