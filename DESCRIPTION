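Package: bayesplacebo
Title: Bayesian Integration Modelling of Placebo Hypoalgesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a Bayesian cue-integration model to trial-level pain ratings
    from two-phase placebo conditioning experiments. Per subject, Gaussian
    prior (treatment expectation) and likelihood (sensory evidence)
    distributions are estimated by maximum likelihood, combined by
    precision weighting into a predicted posterior pain percept, and
    compared against a no-treatment-experience Null model through the
    conjugate Gaussian marginal likelihood. Evidence is aggregated across
    subjects with Bayes factors, the positive evidence ratio, and
    random-effects Bayesian model selection (variational Dirichlet scheme
    with exact two-model exceedance probabilities). Includes a seeded
    simulator of the two-group (constant versus temperature-jittered
    conditioning) experiment for parameter-recovery studies, plus the
    behavioural statistics: placebo effects, variability-based sub-sample
    selection, correlations, and the regression of placebo effect on prior
    and likelihood spread.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
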