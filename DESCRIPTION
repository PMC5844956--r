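Package: MotionNoise
Title: Noise Signatures of Head Motion in Resting-State fMRI Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the stochastic structure ("noise signature") of
    involuntary head motion recorded during resting-state fMRI. Starting from
    the six rigid-body motion parameters produced by standard volume
    registration, the package derives uniformly resampled linear and angular
    speed profiles, estimates their scaling exponents by detrended
    fluctuation analysis (DFA), summarizes the per-subject exponent
    distributions with maximum-likelihood Gamma fits whose scale parameter is
    a noise-to-signal ratio, and compares clinical subgroups against
    age-matched bootstrap subsamples of a larger reference pool using
    two-sample Kolmogorov-Smirnov tests. A synthetic-cohort generator
    produces multi-site motion data with controllable noise color
    (fractional Gaussian noise and fractional Brownian motion with known
    Hurst exponents) for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    signal,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
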