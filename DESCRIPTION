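Package: popmodes
Title: Collective Modes of Neural Population Activity via Tree-Emission Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits hidden Markov models with Chow-Liu tree emission
    distributions to binary spike rasters of neural populations, identifying
    discrete collective activity modes. Provides Baum-Welch fitting with
    shrinkage regularization, Viterbi decoding, cross-validated selection of
    the number of modes, per-mode entropy and spike-count distributions,
    transition-entropy and dwell-time summaries, Fisher LDA mode
    discriminability, repeat-based information-efficiency and reproducibility
    measures with randomized controls, spike- and mode-triggered stimulus
    averages with linear-nonlinear simulation, and seedable synthetic
    ground-truth generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
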