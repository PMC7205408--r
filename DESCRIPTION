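Package: niadhere
Title: Non-Inferiority Trial Simulation Under Treatment Non-Adherence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates two-arm non-inferiority trials with a binary
    endpoint under eighteen distinct patterns of treatment non-adherence,
    using a potential-outcomes data-generating mechanism with an optional
    Beta-distributed confounder. Analyzes simulated trials with
    intention-to-treat, per-protocol, inverse-probability-weighted and
    instrumental-variable (structural mean model) risk-difference
    estimators, applies the non-inferiority decision rule to the upper
    confidence bound, and runs Monte-Carlo experiments to estimate
    empirical type-I error, power and the sample size required to
    maintain power as adherence falls. Includes a closed-form sample-size
    formula for the fully adherent design and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
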