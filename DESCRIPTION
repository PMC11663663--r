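Package: brdiva
Title: Boundedly Rational Divergent Autoencoder Models of Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial simulation of human category learning with the
    divergent autoencoder (DIVA) and its boundedly rational variational
    extension (BR-DIVA), in which a beta-weighted Kullback-Leibler penalty
    trades representational precision against coding cost. Implements the
    eight binary three-feature stimuli and the six structurally distinct
    category assignments of the classic six-problems benchmark, a simulated
    participant protocol (random weight initialisation, blocked random
    presentation, response-before-update scoring), and the statistical
    analyses used to summarise the simulations: accuracy aggregation,
    dummy-coded least-squares regressions, paired and pooled two-sample
    t-tests, learning curves, hidden-layer representation geometry, and
    rule-versus-exception error curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
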