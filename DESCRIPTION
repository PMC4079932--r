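Package: healthexp
Title: Healthy Life Expectancy by the Sullivan Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating healthy and unhealthy life expectancy in
    older populations. Builds sex-specific abridged life tables from
    registered deaths and mid-period population counts using the Chiang
    method, with sampling variances for death probabilities and life
    expectancies. Estimates design-based prevalence of dichotomized health
    states (poor self-rated health and three levels of self-reported
    functional limitation) from complex household-survey microdata, with
    Taylor-linearized variances, design effects, and design-adjusted
    (Rao-Scott) chi-square tests. Decomposes life expectancy at exact ages
    into healthy and unhealthy years via the Sullivan method, attaches
    delta-method confidence intervals, and tests between-group (e.g.,
    female-male) differences. Includes a synthetic-data generator
    (Gompertz mortality registry, two-stage cluster survey with a latent
    ordered-logistic severity model) with exact ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
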