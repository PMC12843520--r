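Package: neuroforecast
Title: EEG Neuroforecasting of Audience Outcomes from Frontal Alpha
    Asymmetry and Inter-Subject Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for forecasting individual, population-level, and
    real-world outcomes from multi-subject EEG recorded during
    naturalistic video viewing. Implements frontal alpha asymmetry
    (log F4 minus log F3 alpha power, via Welch and Morlet estimators),
    inter-subject correlation of alpha-power envelopes on mid-central
    channels, rolling-window moment-to-moment forecasting with bootstrap
    confidence intervals, crossed random-intercept mixed models and
    video-level regressions, and Monte Carlo power analysis for
    video-level correlations. Ships a fully parameterized synthetic-study
    generator (20-channel 10-20 EEG with latent interest-driven
    asymmetry, shared stimulus-locked envelopes, pink noise, blinks, and
    matched behavioral, population, and funding-outcome tables) so every
    stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
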