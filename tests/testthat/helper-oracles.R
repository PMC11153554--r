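# Independent naive oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Pivoted Gram-Schmidt on the rows of X: repeatedly pick the largest-norm
# row, normalise it, project it out of every row. Returns the unit bases
# and the final residual matrix.
oracle_pivoted_gs <- function(x, steps = ncol(x), tol = 1e-10) {
  r <- x
  bases <- list()
  limit <- tol * max(sqrt(rowSums(x^2)))
  for (s in seq_len(steps)) {
    norms <- sqrt(rowSums(r^2))
    i <- which.max(norms)
    if (norms[i] <= limit) break
    b <- r[i, ] / norms[i]
    bases[[s]] <- b
    for (j in seq_len(nrow(r))) {
      r[j, ] <- r[j, ] - sum(r[j, ] * b) * b
    }
  }
  list(bases = do.call(rbind, bases), residual = r)
}

# Step-by-step scalar trace of the supervised application recurrence
# (project, correct by the step gain, accumulate through the output part),
# an independent route from the implementation's cached affine readout.
oracle_chain_trace <- function(model, x_row) {
  p <- model$p
  r <- x_row - model$input_means
  yhat <- 0
  for (s in seq_len(model$m)) {
    k_in <- sum(r * model$directions[s, 1:p])
    yhat <- yhat + model$gains[s] * k_in * model$directions[s, p + 1]
  }
  yhat + model$output_means
}

# Independent recomputation of the calibrated step gains via explicit
# normal equations, for cross-checking the fitted readout.
oracle_gains <- function(model, x, y) {
  p <- model$p
  h <- sweep(x, 2, model$input_means) %*% t(model$directions[, 1:p, drop = FALSE])
  reg <- sweep(h, 2, model$directions[, p + 1], "*")
  drop(solve(crossprod(reg), crossprod(reg, y - model$output_means)))
}

# Hand-rolled trace of the cascade application chain for one row.
oracle_cascade_trace <- function(model, x_row) {
  y_prev <- NULL
  for (l in seq_len(model$config$levels)) {
    lvl <- model$levels[[l]]
    v <- if (l == 1L) x_row else c(x_row, y_prev)
    e <- apply(lvl$basis$exponents, 1L, function(ex) prod(v^ex))
    y_prev <- oracle_chain_trace(lvl$sgtm, e / lvl$scaler$scale)
  }
  y_prev
}

# Held-out RMSE of the ordinary-least-squares oracle.
oracle_ols_rmse <- function(x, y, xh, yh) {
  beta <- stats::lm.fit(cbind(1, x), y)$coefficients
  sqrt(mean((yh - drop(cbind(1, xh) %*% beta))^2))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
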