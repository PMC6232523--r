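Package: lcdmDE
Title: Log-Linear Cognitive Diagnosis Models via EM and Differential
    Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the log-linear cognitive diagnostic model (LCDM) to binary
    item-response data by marginal maximum likelihood, using either the
    classical expectation-maximization (EM) algorithm or a hybrid estimator
    in which the M-step item-parameter update is carried out by a
    derivative-free Differential Evolution (DE) global optimizer.  Includes
    a reusable box-constrained DE maximizer, posterior attribute
    classification (MAP and EAP), MADcor and SRMSR global fit indices,
    Q-matrix and correlated-attribute simulators, and a Monte-Carlo
    parameter-recovery study framework reporting classification accuracy,
    relative bias and root mean squared error.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
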