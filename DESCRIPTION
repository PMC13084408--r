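Package: burstlink
Title: Trial-by-Trial Coupling of Visual Burst Features and Saccadic Reaction Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking single-neuron visual-response features
    (onset latency, baseline-subtracted burst strength, pre-stimulus state) to
    trial-by-trial saccadic reaction-time variability in superior colliculus
    (SC) and primary visual cortex (V1) recordings. Provides causal-kernel
    single-trial firing-rate estimation, a peak-and-backward-walk latency
    detector, visual/visual-motor functional classification with a visuomotor
    index, per-neuron Spearman correlation batteries with non-parametric
    population tests, a Gamma log-link mixed model of reaction time with
    neuron-level random intercepts fitted by a Laplace approximation,
    current-source-density input-layer identification, spike-waveform width
    typing, and an inhomogeneous-Poisson session simulator with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mclust
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
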