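Package: snarezip
Title: Mechanical Unzipping and Zippering Analysis of Single SNARE Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Polymer-physics modelling and trace analysis for single-molecule
    magnetic-tweezers experiments on DNA-tethered neuronal SNARE complexes.
    Provides a worm-like-chain extension model for the pulling construct in
    each conformational state (fully zippered, linker-open, half-zippered,
    unzipped, SNAP-25 dissociated), a kinetic Monte Carlo simulator with
    Bell-equation force-dependent rates, step detection and quality control
    for force-ramp cycles, censored-exponential dwell-time analysis with
    Bell fits and coarse-grained energy-landscape reconstruction, Gaussian
    mixture decomposition of high-speed extension distributions with a
    three-state equilibrium model, and Gaussian-emission hidden Markov
    idealization of 1.2 kHz traces with per-transition kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    mclust,
    zoo,
    ggplot2,
    generics,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
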