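---
title: "SGTM cascades: model, numerical choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SGTM cascades: model, numerical choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgtmcascade)
```

This vignette is the package's own account of the method it implements:
what the model is, which assumptions it leans on, which parameters matter,
where the design was genuinely open and what we chose, and what the method
cannot do.

## The SGTM building block

The Successive Geometric Transformations Model approximates a response
surface without iterative weight optimisation. Write the training sample as
rows $x_i \in \mathbb{R}^p$ and, in supervised mode, augment each row with
its centred target, $z_i = [x_i - \bar x \,\vert\, y_i - \bar y]$. Training
is a pivoted Gram–Schmidt pass over the rows:

1. pick the residual row with the largest Euclidean norm (the longest axis
   of the scattering ellipsoid) and normalise it into a unit base
   direction $b^{(S)}$;
2. compute every row's projection coefficient $k^{(S)}_i = z_i \cdot
   b^{(S)}$ and subtract $k^{(S)}_i b^{(S)}$ from every row;
3. repeat until the residual matrix is numerically zero or $m$ steps are
   done.

The directions are orthonormal, ordered by captured energy, and for a
full-rank matrix the residual vanishes after as many steps as the space has
dimensions — which makes the unsupervised mode a lossless decomposition:
`sgtm_reconstruct()` inverts `sgtm_transform()` on the training matrix to
machine accuracy.

Two details are worth stating because the geometric description leaves them
open:

* **Normalisation.** We store unit base directions and define $k$ as a
  plain dot product. Defining $k$ with an unnormalised base and dividing by
  its norm is algebraically identical; only the unit-base convention makes
  the subtraction an exact orthogonal projection and the decomposition
  exactly invertible.
* **Intercept.** All columns — inputs and targets — are centred by their
  training means, and the means are added back at prediction and
  reconstruction time. No constant column is ever emitted by the feature
  expansion; the intercept of every downstream polynomial is the
  composition of these means.

### The application-mode readout

At application time the target component of $z$ is unknown, so the exact
coefficient $k^{(S)}$ cannot be formed. The classical remedy is a per-step
scalar correction from the input-only coefficient
$k_{\mathrm{in}}^{(S)} = (x - \bar x)\cdot b_{\mathrm{in}}^{(S)}$ to the
exact one, fitted by least squares over the training rows; the model stores
these scalars (`alphas`). The per-step formula, however, is exact only when
the *input parts* $b_{\mathrm{in}}^{(S)}$ of the directions are mutually
orthogonal — the full augmented directions are orthonormal, their input
parts generally are not. A single corrected sweep therefore leaves a
systematic error that no amount of data removes (on noiseless linear
targets it plateaus around $R^2 \approx 0.7$), and naive fixes fail in
characteristic ways: iterating the sweep diverges when a fitted correction
over-relaxes, and solving the sweep's stationary condition degenerates to
the mean predictor whenever the output direction lies inside the span of
the retained steps.

The package therefore calibrates all step corrections **jointly**: the
prediction is $\hat y = \bar y + \sum_S \gamma_S\, k_{\mathrm{in}}^{(S)}\,
b_{\mathrm{out}}^{(S)}$, and the gains $\gamma_S$ solve one least-squares
fit of the centred training targets on the per-step contribution profiles.
The stored `alphas` are exactly the diagonal approximation of these normal
equations; the joint solve is the same idea carried to completion. Three
consequences we rely on throughout:

* with all $m = p$ steps retained, the readout coincides with ordinary
  least squares of $y$ on the inputs — noiseless linear (and, after
  expansion, noiseless quadratic) targets are recovered exactly;
* a step whose direction has zero output part has an identically zero
  profile and keeps $\gamma_S = 0$: it cannot influence predictions;
* requesting more steps than the inputs can identify is harmless — aliased
  gains are zeroed instead of amplifying noise.

### Hidden neurons

`m` (the "number of hidden neurons") is the number of retained steps.
Because steps arrive in descending energy order, truncation removes the
smallest, noise-dominated components first; `m` trades variance against
capacity exactly as the number of components does in principal-component
regression. `"full"` retains $p$ steps — the input space is
$p$-dimensional, so at most $p$ hidden coefficients are identifiable from
the inputs alone; later steps of the augmented orthogonalisation carry only
output-residual energy. `sweep_hidden_neurons()` scans a grid of `m` values
against a holdout sample and returns the error minimum (ties to the
smaller, cheaper value).

## The cascade

`cascade_fit(train, levels = L, degree = 2, ...)`:

1. the training rows are shuffled (seeded) and cut into $L$ near-equal
   disjoint blocks, one per level;
2. level 1: expand block 1's features with all monomials up to the
   configured degree, fit a max-abs scaler *on the expanded matrix*, fit a
   supervised SGTM;
3. level $\ell > 1$: run block $\ell$'s raw features through levels
   $1..\ell-1$ in pure inference mode, append the resulting prediction as
   the single extra attribute `y_prev`, then expand / scale / fit against
   the block's true targets;
4. application mode repeats the same chain level by level; the last
   level's output is the prediction.

Only the *latest* prediction is carried forward — the chain is Markov in
one scalar — so each level adds exactly one attribute and the composed
response surface doubles its degree per level: $2^L$ in the original
variables. That is the point of the construction: degree-$2^L$ capacity
from $L$ cheap quadratic fits, rather than one fit on the astronomically
wide degree-$2^L$ expansion.

Open choices we fixed, and why:

* **Partition.** Near-equal blocks after a seeded shuffle, remainder rows
  to the earliest blocks. Equal parts keep every level equally informed;
  shuffling guards against ordered inputs.
* **Scaler placement.** One max-abs scaler per level, fitted on that
  level's *expanded* training block (the appended `y_prev` participates).
  Expansion products have wildly different ranges; scaling the raw inputs
  instead would leave the products untamed. The target itself is never
  scaled — only centred by the SGTM.
* **Each level trains only on its own block.** No repetition, no
  refitting of earlier levels.
* **Shared `hidden_neurons`.** One value for all levels; the levels' input
  widths differ by one attribute, so a shared budget is meaningful.
* **Degree default 2.** Higher per-level degrees widen the input
  explosively and invite overfitting; depth, not per-level degree, is the
  intended capacity dial.

## From the neural form to one polynomial

Each trained level is *affine* in its scaled expanded features — the SGTM
readout is affine and scaling is linear. `extract_affine()` exploits this:
probing the level with the zero vector and the unit test signals (the rows
of a diagonal matrix) reads off the intercept and every weight exactly, and
a superposition check on extra probes guards against a non-affine map being
passed in. `level_polynomial()` attaches those weights to the level's
monomials and folds the (affine) scaling in symbolically, so its
coefficients refer to the raw variables. `compose_polynomial()` then
substitutes level $\ell-1$'s polynomial for `y_prev` in level $\ell$'s,
with exact expansion; the result evaluates to the cascade's prediction
within a relative $10^{-8}$ (asserted in the test suite on a thousand
seeded points).

Numerical conventions: the monomial order is frozen (ascending total
degree, then descending lexicographic exponent vectors, so the first $n$
terms are the variables themselves); coefficients below $10^{-12}$ in
magnitude are pruned from emitted polynomials (configurable); composition
is refused above 6 input features by default because the term count of a
degree-$2^L$ polynomial in $p$ variables grows combinatorially — the
neural form remains available at any width.

## Model selection and metrics

`compute_metrics()` reports the four residual summaries MRE (worst
absolute residual), MAE, MSE and MedAE (median absolute residual; mean of
the two middle values for even $n$). `select_optimal_levels()` implements
the optimal-complexity rule: grow the cascade while held-out error falls,
select the depth at the minimum (ties to the shallower model); an
early-stop mode walks the sequence and stops at the first increase, which
agrees with the argmin on unimodal profiles. Selection uses MAE by default
(MSE available). Cross-validation (`kfold_cv`, default $k = 5$) shuffles
rows under the seed into near-equal folds and reports across-fold means
and *sample* standard deviations of every metric.

## Synthetic data: what it emulates, what it does not

Two seeded generators make every stage testable without external data:

* `make_polynomial_dataset()` draws features i.i.d. uniform on $[-1, 1]$
  and a target that is an exact polynomial of known total degree with
  seeded coefficients on *all* monomials (uniform in
  $[-c, c]$, $c$ = `coefficient_scale`, default 1), plus optional Gaussian
  noise. Returning the generating polynomial enables parameter-recovery
  tests: noiseless surfaces representable by the fitted architecture must
  be recovered to numerical accuracy.
* `make_healthcare_like()` emulates the *shape* of a wearable-sensor
  heart-rate table: 18 correlated features (seeded random covariance,
  condition number about 100, max-abs-bounded into $[-1, 1]$ so the
  quadratic expansion stays tame) and a positive bounded target,
  $72 + 18\tanh(\text{smooth signal})$ beats per minute with
  heteroscedastic noise. It does not emulate physiological semantics,
  real marginals, discreteness, or missingness — passing tests on it shows
  the pipeline digests correlated, realistically scaled tables, not that
  it predicts real heart rates.

The bounded-feature convention mirrors max-abs-scaled real data and is why
the generators' surfaces are numerically benign under expansion.

## Known limitations

* **Depth multiplies degree, not dimension.** A level beyond the first has
  $1 + \binom{p+1+2}{2} - 1$ free coefficients — 10 for $p = 2$ — while
  the space of degree-4 polynomials in two variables has dimension 15. A
  *generic* quartic surface is therefore **not** representable by a
  2-level quadratic cascade, however much data is available; what the
  composition guarantees is that the model *reaches* degree $2^L$ along
  the one direction carried by `y_prev`, not that it spans the full
  degree-$2^L$ space. On generic quartics a second level helps (held-out
  error drops measurably) but cannot drive the error to zero. Users
  needing a full low-degree basis should raise `degree` instead of
  `levels`.
* Deep cascades with small data fail loudly: each level needs its own
  block, and per-block sample sizes shrink as $N/L$. When per-level blocks
  get too small relative to the expanded width, held-out error rises
  sharply — that is the regime the optimal-complexity rule exists to
  detect.
* The cascade is inherently sequential; levels cannot be trained in
  parallel.
* Only scalar targets are exercised seriously; multi-output support is a
  pass-through of the same algebra.

## Problem sizes used by the tests and the acceptance script

The suite exercises decompositions up to $200 \times 20$, oracle
comparisons over 50 seeded $30 \times 6$ matrices, a $N = 5000$ quartic
benchmark, thousand-point polynomial-equivalence checks, and
heart-rate-like tables of a few hundred to a few thousand rows — sizes at
which every property under test has converged while the whole suite runs
in seconds. The acceptance script fits 2- and 3-level cascades on 600
seeded rows, which is ample for the degree-doubling law it measures (the
law is generic: it holds for any fit whose top-degree coefficients are
non-zero).
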