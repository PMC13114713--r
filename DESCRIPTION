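Package: splitquant
Title: Sequential Splitting Designs for Extreme Quantile Estimation from
    Binary Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of extreme quantiles (risk levels of order 1e-3) of a
    latent tolerance or resistance distribution when each trial only reveals
    whether the latent variable exceeded the tested level.  Implements a
    multilevel-splitting sequential design that decomposes the rare event into
    a ladder of moderate conditional exceedance events, with generalized
    Pareto and Weibull tail models, a constrained backward-consistency
    (dual-criterion) parameter estimator adapted to binary stage data, and a
    naive Bernoulli maximum-likelihood baseline.  Ships the classical
    comparator procedures used in quantal-response settings (Dixon-Mood
    staircase, continual reassessment method with a Beta prior, de Valk's
    complete-data extreme quantile estimator), neighborhood-based bounds for
    deviations from the generalized Pareto model, and a seed-driven
    replication harness with stage-log persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
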