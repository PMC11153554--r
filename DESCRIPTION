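Package: sgtmcascade
Title: Non-Iterative SGTM Cascade Regression with Polynomial Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-iterative regression based on the Successive Geometric
    Transformations Model (SGTM): a neural-like structure trained by pivoted
    Gram-Schmidt orthogonalisation instead of iterative weight optimisation,
    combined with quadratic Kolmogorov-Gabor polynomial input expansion and a
    cascade ensemble in which each level is trained on its own partition of
    the data and receives the previous level's prediction as one extra
    attribute. Includes the transition from the neural form to an explicit
    polynomial of degree 2^L via diagonal test-signal probing and symbolic
    composition, max-abs preprocessing, error metrics, optimal-complexity
    model selection, hidden-neuron sweeps, k-fold cross-validation, seeded
    synthetic-data generators, CSV and JSON model input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
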