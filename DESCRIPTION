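Package: valuenorm
Title: Divisive Normalization Models of Neural Value Coding in Cued-Lottery Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for relative-value coding in
    single-neuron firing rates recorded (or simulated) during a risky/safe
    cued-lottery task. Generates synthetic sessions with block-structured
    payoffs, softmax choice behavior and Poisson spiking; screens neuron-epoch
    activities for relative-value or choice coding by exhaustive AIC variable
    selection; fits thirteen firing-rate models (divisive normalization,
    fractional, difference, range-normalization and linear alternatives) by
    multi-restart nonlinear least squares; and reproduces population-level
    model selection, free-versus-forced context attenuation, parameter
    dispersion and risk-attitude analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    car,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
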