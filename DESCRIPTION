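Package: locomod
Title: Locomotion-State Modulation of Visual Cortical Population Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how locomotor state modulates stimulus coding in
    two-photon calcium-imaging recordings of mouse visual cortex. Provides a
    synthetic session generator with planted ground truth (running bouts,
    direction-tuned drifting-grating responses, state-dependent trial noise,
    shared-gain noise correlations), rolling-baseline dF/F computation, trial
    extraction with locomotor-state labelling and class balancing, running-speed
    tuning classification (quantile-binned curves, permutation Levene test,
    Spearman monotonicity, constrained Gaussian model selection), state-conditioned
    multinomial logistic decoding with trial-shuffling and neuron-exclusion
    controls, a trial-to-trial response reliability statistic, a leaky
    integrate-and-fire simulation of membrane-noise effects on firing rate and
    reliability, and a deterministic end-to-end replay pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
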