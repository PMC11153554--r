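test_that("unsupervised fit on axis-aligned rows recovers the axes in norm order", {
  x <- matrix(c(3, 0, 0, 2, 0, 0), 3, 2, byrow = TRUE)
  fit <- sgtm_fit(x, center = FALSE)
  expect_equal(fit$m, 2L)
  expect_equal(fit$directions, matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(fit$base_norms, c(3, 2))
  # residual after both steps is the zero matrix: reconstruction is exact
  expect_equal(sgtm_reconstruct(fit, sgtm_transform(fit, x)), x, tolerance = 1e-12)
})

test_that("equal maximal norms break ties to the smallest row index", {
  fit <- sgtm_fit(diag(2), center = FALSE)
  expect_equal(fit$base_row_indices[1], 1L)
})

test_that("transform yields axis coordinates and respects Parseval on the toy model", {
  fit <- sgtm_fit(matrix(c(3, 0, 0, 2, 0, 0), 3, 2, byrow = TRUE), center = FALSE)
  k <- sgtm_transform(fit, matrix(c(3, 4), 1))
  expect_equal(drop(k), c(3, 4))
  expect_equal(sum(k^2), 25)
})

test_that("transform of the training matrix reproduces the recorded coefficients", {
  set.seed(31)
  x <- matrix(rnorm(60), 12, 5)
  fit <- sgtm_fit(x)
  k <- sgtm_transform(fit, x)
  # the base row of step 1 must map to (base_norm, 0, 0, ...)
  i <- fit$base_row_indices[1]
  expect_equal(k[i, 1], fit$base_norms[1], tolerance = 1e-10)
  expect_equal(k[i, -1], rep(0, fit$m - 1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("full decomposition drives the residual to zero and inverts exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(100), 20, 5)
    fit <- sgtm_fit(x)
    expect_equal(fit$m, 5L)
    xhat <- sgtm_reconstruct(fit, sgtm_transform(fit, x))
    expect_lt(max(abs(xhat - x)), 1e-9)
  }
})

test_that("bases agree with an independent naive pivoted Gram-Schmidt up to sign", {
  set.seed(7)
  x <- matrix(rnorm(100), 20, 5)
  fit <- sgtm_fit(x, center = FALSE)
  ref <- oracle_pivoted_gs(x)
  expect_equal(nrow(ref$bases), fit$m)
  agree <- abs(rowSums(fit$directions * ref$bases)) # |cos| of paired bases
  expect_equal(agree, rep(1, fit$m), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(ref$residual)), 1e-9)
})

test_that("truncated coordinates obey the Bessel inequality", {
  set.seed(11)
  x <- matrix(rnorm(160), 20, 8)
  fit <- sgtm_fit(x, m = 4)
  k <- sgtm_transform(fit, x)
  centred <- sweep(x, 2, fit$input_means)
  expect_true(all(rowSums(k^2) <= rowSums(centred^2) + 1e-10))
})

test_that("zero coordinates reconstruct the row-repeated column means", {
  set.seed(12)
  x <- matrix(rnorm(40), 8, 5)
  fit <- sgtm_fit(x, m = 3)
  xhat <- sgtm_reconstruct(fit, matrix(0, 2, 3))
  expect_equal(xhat, matrix(fit$input_means, 2, 5, byrow = TRUE), tolerance = 1e-12)
})

test_that("fitted step sequences are orthonormal with non-increasing energy", {
  for (seed in 1:8) {
    set.seed(100 + seed)
    n <- sample(5:30, 1)
    p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    supervised <- seed %% 2 == 0
    fit <- if (supervised) sgtm_fit(x, rnorm(n)) else sgtm_fit(x)
    gram <- tcrossprod(fit$directions)
    expect_lt(max(abs(gram - diag(fit$m))), 1e-8)
    expect_true(all(diff(fit$base_norms) <= 1e-10))
  }
})

test_that("fitting is deterministic: identical inputs give bit-identical models", {
  set.seed(21)
  x <- matrix(rnorm(120), 24, 5)
  y <- rnorm(24)
  expect_identical(sgtm_fit(x, y), sgtm_fit(x, y))
  expect_identical(sgtm_fit(x), sgtm_fit(x))
})

test_that("constant targets collapse to the mean predictor", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4)
  fit <- sgtm_fit(x, rep(7, 10))
  expect_equal(predict(fit, matrix(rnorm(12), 3, 4)), rep(7, 3), tolerance = 1e-10)
  # zero retained steps also fall back to the training mean
  fit0 <- sgtm_fit(x, rnorm(10) + 2, m = 0)
  expect_equal(fit0$m, 0L)
  expect_equal(predict(fit0, x), rep(fit0$output_means, 10), tolerance = 1e-12)
})

test_that("a step with zero output component contributes nothing to predictions", {
  set.seed(6)
  x <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  fit <- sgtm_fit(x, y, m = 2)
  fit$directions[, 4] <- 0    # null both steps' output parts
  cal <- sgtmcascade:::calibrate_readout(
    fit, sweep(x, 2, fit$input_means), y - fit$output_means)
  fit$gains <- cal$gains
  fit$app_weights <- cal$app_weights
  expect_equal(predict(fit, x), rep(fit$output_means, 10), tolerance = 1e-10)
})

test_that("calibrated step gains solve the joint normal equations", {
  set.seed(14)
  x <- matrix(rnorm(200), 50, 4)
  y <- x[, 1] - 0.5 * x[, 3] + rnorm(50, sd = 0.2)
  fit <- sgtm_fit(x, y)
  expect_equal(fit$gains, oracle_gains(fit, x, matrix(y)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("supervised accuracy is close to the least-squares oracle", {
  set.seed(42)
  x <- matrix(rnorm(500 * 5), 500, 5)
  w <- c(2, -1, 0.5, 0, 1)
  y <- drop(x %*% w) + rnorm(500, sd = 0.1)
  xh <- matrix(rnorm(500 * 5), 500, 5)
  yh <- drop(xh %*% w) + rnorm(500, sd = 0.1)
  fit <- sgtm_fit(x, y)
  expect_lt(rmse(yh, predict(fit, xh)), 1.10 * oracle_ols_rmse(x, y, xh, yh))
  # noiseless linear data: essentially perfect held-out fit
  fit0 <- sgtm_fit(x, drop(x %*% w))
  yh0 <- drop(xh %*% w)
  expect_gt(1 - mean((yh0 - predict(fit0, xh))^2) / var(yh0), 0.999)
})

test_that("predictions equal a naive row-by-row trace of the correction chain", {
  set.seed(8)
  x <- matrix(rnorm(300), 60, 5)
  y <- 2 * x[, 1] - x[, 2] + rnorm(60, sd = 0.1)
  fit <- sgtm_fit(x, y)
  rows <- c(3, 27, 55)
  for (i in rows) {
    expect_equal(predict(fit, x[i, , drop = FALSE]),
                 oracle_chain_trace(fit, x[i, ]), tolerance = 1e-12)
  }
})

test_that("invalid inputs are rejected with clear errors", {
  expect_error(sgtm_fit(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(sgtm_fit(matrix(c(1, NA), 1, 2)), "non-finite")
  expect_error(sgtm_fit(matrix(1:4, 2, 2), c(1, NaN)), "non-finite")
  set.seed(1)
  x <- matrix(rnorm(20), 5, 4)
  fit <- sgtm_fit(x, rnorm(5))
  expect_error(predict(fit, matrix(1, 2, 3)), "columns")
  ufit <- sgtm_fit(x)
  expect_error(sgtm_transform(ufit, matrix(1, 2, 2)), "columns")
  expect_error(sgtm_reconstruct(ufit, matrix(1, 2, 2)), "columns|steps")
  expect_error(sgtm_fit(x, rnorm(5), m = 6), "exceed")
})
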