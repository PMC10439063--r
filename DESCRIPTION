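Package: latentnorms
Title: Rating Norms from Cumulative Link Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for norming items rated on ordinal Likert scales by
    extracting item (and participant) random effects from cumulative link
    mixed models (CLMMs). Provides a maximum-likelihood equal-variance
    CLMM with crossed random intercepts fitted by the Laplace
    approximation, a Bayesian distributional CLMM that additionally norms
    latent standard deviations via a discrimination parameter, baseline
    norming methods (raw means, within-participant z-scores, linear mixed
    models), simulation generators for threshold-based response patterns
    and non-normal latent distributions, and evaluation procedures
    (parameter recovery, scaled errors, split-half consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    lme4,
    statmod,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
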