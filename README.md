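# sgtmcascade

Non-iterative cascade regression for numeric tabular data, built from
SGTM neural-like structures (Successive Geometric Transformations Model)
with quadratic Kolmogorov–Gabor input expansion — and a lossless transition
from the fitted "neural" form to one explicit polynomial.

## The problem and the method

Fitting smooth nonlinear response surfaces on large tables (the motivating
application is predicting heart rate from 18 wearable-sensor attributes)
usually forces a choice between slow iterative training, opaque models, or
polynomial feature maps whose width explodes with the degree: the full
degree-*k* expansion of *n* inputs has `choose(n + k, k) − 1` terms, already
189 columns for *n* = 18 at *k* = 2 and hopeless at *k* = 8.

This package implements a cascade that gets high-degree capacity from
cheap quadratic pieces:

1. **SGTM** — a training algorithm with no iterative weight optimisation.
   Appending the centred target to each input row and repeatedly (i) taking
   the largest-norm row as a unit base direction `b^(S)`, (ii) projecting
   every row on it (`k^(S) = x · b^(S)`), and (iii) subtracting the
   projection, is a pivoted Gram–Schmidt pass that orders orthonormal
   directions by captured energy (principal-component-like). Truncating to
   the first *m* directions — the *hidden neurons* — drops
   noise-dominated components. At application time the hidden coefficients
   are recovered from the input components alone and corrected by
   least-squares gains (with all *m* retained, the readout coincides with
   ordinary least squares on the inputs).
2. **Kolmogorov–Gabor expansion** — each level sees all monomials of its
   inputs up to degree 2 (`x_i`, `x_i^2`, `x_i x_j`), max-abs-scaled, so a
   linear-in-parameters SGTM fits a quadratic surface.
3. **Cascade** — the training rows are split into *L* disjoint blocks.
   Level 1 trains on block 1. Every later level pushes its own block
   through the already-trained chain, appends the resulting prediction
   `y_prev` as *one* extra attribute, expands, and trains against the true
   targets. Since each level is quadratic in `(x, y_prev)`, the composed
   surface has degree `2^L` in the original inputs (response-surface
   linearization) while every fit stays linear.
4. **Interpretability** — each trained level is affine in its expanded
   features, so probing it with zero and unit test signals reads off its
   intercept and weights exactly; substituting level *ℓ−1*'s polynomial
   into level *ℓ*'s and expanding symbolically yields a single explicit
   polynomial that reproduces the cascade's predictions to floating-point
   accuracy.
5. **Model selection** — the four errors MRE / MAE / MSE / MedAE, the
   optimal-complexity rule for the cascade depth (stop where held-out error
   stops decreasing), a brute-force hidden-neuron sweep, and k-fold
   cross-validation.

## Worked example

A quartic surface in two variables with mild noise; the cascade depth is
chosen by the optimal-complexity rule, and the selected model is collapsed
to its explicit polynomial:

```r
library(sgtmcascade)

gen <- make_polynomial_dataset(5000, n_features = 2, degree = 4,
                               noise_sd = 0.05, seed = 42)
sp  <- split_train_test(gen$data, test_fraction = 0.30, seed = 42)

errs <- sapply(1:4, function(L) {
  fit <- cascade_fit(sp$train, levels = L, seed = 42)
  compute_metrics(sp$test$y, predict(fit, sp$test$x))$mae
})
round(errs, 4)
#> [1] 0.1536 0.1195 0.1203 0.1197
select_optimal_levels(errs)
#> [1] 2

best <- cascade_fit(sp$train, levels = 2, seed = 42)
compute_metrics(sp$test$y, predict(best, sp$test$x))
#> <metric_report> n = 1500
#>   MRE 0.596722 | MAE 0.119488 | MSE 0.0236886 | MedAE 0.0967899

p <- compose_polynomial(best)
poly_degree(p); nrow(poly_to_table(p))
#> [1] 4
#> [1] 15
```

Held-out MAE drops from 0.154 (one quadratic level) to 0.119 at two
levels and stops improving, so the rule selects depth 2; the composed
model is a single degree-4 polynomial with 15 terms whose evaluation
equals `predict(best, ...)`. A deeper dive — assumptions, parameter
choices, known limitations — is in `vignettes/sgtm-cascade-methods.Rmd`.

The same pipeline is scriptable from a shell (see `inst/cli/sgtmcascade`):

```sh
sgtmcascade simulate --kind healthcare --n 2000 --seed 7 --out d.csv
sgtmcascade train --data d.csv --target heart_rate --levels 3 --seed 7 --out m.json
sgtmcascade predict --model m.json --data d.csv --out p.csv
sgtmcascade extract-poly --model m.json --out poly.csv   # small p only
```

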