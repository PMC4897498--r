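Package: gibbs2pno
Title: Gibbs Sampling for the Two-Parameter Normal Ogive IRT Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully Bayesian estimation of the two-parameter normal ogive
    (2PNO) item response model by Gibbs sampling with truncated-normal data
    augmentation. Provides the exact full-conditional samplers for the
    augmented data, person traits and item parameters, a chain runner with a
    block-decomposed execution scheme (an r x c partition of the response
    matrix with per-block random streams and ordered partial-sum reductions),
    batch-means Monte Carlo standard errors, item response curve and trait
    density summaries, a synthetic response generator with known truth for
    parameter-recovery studies, and a command-line interface with
    speedup/efficiency benchmark arithmetic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
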