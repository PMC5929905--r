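Package: ascfc
Title: Additive Signal Change Analysis of Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disambiguates changes in functional connectivity between two
    states by testing whether an observed change in correlation, together
    with the accompanying changes in variance, can be explained by Additive
    Signal Changes (ASC): the addition of new signal to the existing node
    signals. Provides deterministic bounds on the attainable state-B
    correlation for the uncorrelated-addition, common-signal and general
    additive classes; a Monte-Carlo null-hypothesis inference procedure over
    the sampled distribution of underlying true covariances (inverse-Wishart
    rejection sampling at an AR-estimated effective degrees of freedom); a
    network-level pipeline with Benjamini-Hochberg false discovery rate
    control and four-way edge classification; and a simulator generating
    two-state validation scenarios with controlled additive-signal structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
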