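Package: endoreg
Title: Mechanistic and Neural Modelling of Endocrine Gland Networks with
    Closed-Loop Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling hormonal regulation as a coupled gland
    network. Provides a mechanistic ordinary-differential-equation simulator
    of signed gland couplings, degradation and secretion responses (including
    the hypothalamic-pituitary-thyroid axis as a preset), a graph-attention
    recurrent forecaster of hormone trajectories trained by backpropagation
    with adaptive-moment updates, and an adaptive closed-loop intervention
    optimizer with multi-objective risk penalties, safety constraints and
    Gaussian Bayesian personalization of patient-specific physiological
    parameters. The simulator doubles as a synthetic-data generator so the
    whole stack builds and tests without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
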