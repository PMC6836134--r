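Package: maskmix
Title: Mixture Modelling and Bayesian Model Comparison for Cued
    Metacontrast Masking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous-report orientation data from
    cued metacontrast-masking experiments. Simulates factorial
    cue-target-onset-asynchrony (CTOA) by stimulus-onset-asynchrony (SOA)
    designs with endogenous (central, 100 percent valid) or exogenous
    (peripheral, chance-valid) pre-cues, decomposes signed report errors
    into Gaussian encoding, uniform guessing and misbinding components
    (G, GU, GUCA, GUNN model family), scores the models by uniform-prior
    marginal likelihood computed with Riemann-grid integration, fits the
    embedded polynomial regression ladder (M1-M21) that tests whether
    attention and masking interact, and provides bootstrap parameter
    inference, masking-function summaries and the ceiling/floor criterion
    tests used to validate such designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
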