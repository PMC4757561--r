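Package: phackcurve
Title: P-Curves Under P-Hacking by Omitted-Variable Bias in Observational
    Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study whether the p-curve (the distribution of
    statistically significant p-values) can distinguish true effects from
    null effects that were p-hacked through specification search in
    observational regression. Provides a calibrated Monte Carlo simulator of
    omitted-variable bias in ordinary least squares, a p-curve construction
    and skew-diagnostic toolkit, a cross-country growth specification-search
    pipeline (null-outcome construction, exhaustive all-subsets model
    vibration, and sequential significance hunting), and a synthetic
    generator of growth-regression tables with a known zero effect of the
    variable of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
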