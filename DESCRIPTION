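Package: polyadapt
Title: Polygenic Adaptation Under Stabilizing Selection with a Moving Optimum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of a highly polygenic quantitative
    trait under Gaussian stabilizing selection, and the analytic theory that goes
    with it. Provides a fast allele-frequency (linkage-equilibrium mean-field)
    engine and a small-scale individual-based engine for cross-validation;
    observables for the response to an instantaneous optimum shift (trait moments,
    per-locus contribution decomposition, substitution classification, time to
    optimum); the stationary diffusion-approximation prediction of the equilibrium
    genetic variance under mutation-selection-drift balance; and the classical
    limits to directional selection (Robertson's 2-Ne bound, Kimura fixation
    probabilities, substitution efficiency across genetic architectures). All
    inputs are synthetic genetic architectures; results are returned as tibbles
    with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
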