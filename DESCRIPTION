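Package: meaburst
Title: Multiparametric Spike-Train Analysis for Microelectrode-Array Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping the electrical activity of cultured neuronal
    networks recorded on microelectrode arrays. Detects single-unit bursts by
    the interspike-interval (max-interval) method, computes a versioned
    204-feature description of network activity in four categories (general
    activity, burst structure, synchronization, oscillation), detects
    population bursts and synchrony metrics (event rate, hamming factor,
    network coefficients of variation), classifies activity phenotypes with a
    single-layer perceptron trained by resilient propagation under
    cross-validation with a chi-squared recognition test, summarises group
    effects as percent-of-control with unpaired t-tests, derives morphometry
    ratios from per-image count tables, models the timing envelope of a
    pulse-modulated stimulation protocol, and simulates developing cortical
    network activity with controllable synchrony, maturation and treatment
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
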