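Package: resilnorm
Title: Resilience Phenotyping from High-Frequency Records via Mixture
    Models and Reaction-Norm Animal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage genetic analysis of resilience from frequently
    recorded phenotypes such as daily feed intake.  Stage one detects
    unrecorded environmental challenges from day-level cross-animal
    variability: a two-component Gaussian mixture is fitted by EM to the
    natural log of the daily coefficient of variation, the number of
    components is confirmed by parametric bootstrap, and the posterior
    probability of the high-variance component gives each day a
    continuous challenge probability.  Stage two uses those
    probabilities as the environmental covariate of a linear
    reaction-norm animal model fitted by EM/average-information REML or
    Gibbs sampling with a pedigree relationship matrix, yielding level
    and environmental-sensitivity breeding values, variance and
    heritability trajectories along the environmental gradient, the
    level-slope genetic correlation with its standard error, a
    likelihood-ratio test against the plain animal model, and a
    three-group resilience classification of animals.  A simulator
    generates pedigrees, challenge-day processes and phenotypes under
    the same model for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
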