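Package: deplete
Title: Depletion-Fishing Analysis and Removal-Effort Planning for Invasive Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing removal (depletion) fishing of invasive reef
    fish such as lionfish. Standardizes dive effort and catch per 1,000 m2,
    fits per-site Leslie depletion regressions to estimate initial abundance
    and catchability with confidence intervals, runs regression diagnostics,
    fits exponential asymptotic removal models (optionally catchability-scaled
    and with a site random effect estimated by maximum likelihood with
    adaptive Gauss-Hermite quadrature), compares models by small-sample AICc,
    and inverts the selected model to plan the dive effort required to reach a
    target percent reduction of the population. Includes a seeded simulator of
    multi-site depletion studies for validation, CSV/JSON input and output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    lmtest,
    pracma,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
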