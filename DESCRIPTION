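Package: latentiv
Title: Bivariate Causal Discovery with Latent Instrumental Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether X causes Y, Y causes X, or a hidden common cause
    drives both, from two observed numeric series alone. Latent instrumental
    variables are approximated by k-means cluster-center series built from X,
    from Y, and from both jointly; a symmetric decision tree over two
    conditional-independence tests (the exact t-test for first-order partial
    correlation for continuous data, a G-test of conditional mutual information
    for discrete data) returns the verdict. Ships structural-causal-model
    simulators (binary Bayesian networks, linear-Gaussian models with
    instruments and a confounder, two-population mixtures sharing one
    mechanism), a k-fold ensemble, a cause-effect-pairs benchmark harness with
    weighted accuracy, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
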