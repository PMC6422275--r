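Package: mataboot
Title: Model-Averaged Tail Area Confidence Intervals with a Studentized
    Bootstrap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frequentist model-averaged confidence intervals for parameters
    shared across a set of candidate normal linear models fitted to balanced
    two-level factorial designs: the full-model Wald interval, the
    model-averaged Wald (MA-Wald) interval, the z- and t-versions of the
    model-averaged tail area Wald (MATA-Wald) interval, the parametric
    percentile bootstrap interval, and a studentized-bootstrap model-averaged
    tail area (MATA-SBoot) interval in which each model's tail probabilities
    are estimated from the bootstrap distribution of its studentized
    estimate. Includes estimation of lognormal cell means with an unbiased
    variance estimator, a synthetic-data generator for randomized-effect
    factorial scenarios, and a scenario-based simulation study reporting
    lower and upper error rates and relative half-widths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
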