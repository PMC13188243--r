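Package: odetransfer
Title: Simulation-Based Transfer Learning for Dynamical-System Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating ordinary-differential-equation derived
    synthetic time-series datasets of controlled size, diversity and noise
    (measurement or environmental, additive or multiplicative), pre-training
    small neural forecasters (LSTM, GRU, CNN, DNN with a two-layer head) on
    them, fine-tuning the head on a target series, and quantifying when
    simulation-based transfer learning beats uninformed deep learning and
    plain ODE calibration. Includes dynamic-time-warping based coherence
    screening of synthetic dynamics against a target series and blocked
    bootstrap confidence intervals for paired forecast comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'noise.R'
    'ode-systems.R'
    'simulate.R'
    'intervals.R'
    'generate.R'
    'windows.R'
    'nn.R'
    'forecast.R'
    'baselines.R'
    'coherence.R'
    'evaluation.R'
    'io.R'
    'orchestration.R'
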