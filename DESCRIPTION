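Package: ribmetric
Title: Welfare-Based Quality Evaluation of Agricultural Index-Insurance
    Contracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate remote-sensing-based agricultural index
    insurance with an explicitly welfare-based quality metric, the
    relative insurance benefit (RIB).  Fits the standard family of
    livestock mortality loss models (linear, cutoff-restricted linear,
    segmented regression with an estimated breakpoint, and conditional
    quantile regression) on standardized index anomalies, prices
    indemnity contracts with a deductible and proportional markup,
    computes expected-utility certainty equivalents under constant
    relative risk aversion, decomposes the insurance benefit into
    state-contingent transfers weighted by the shadow value of money,
    classifies payout errors (false negatives by severity, false
    positives), and compares contracts by RIB alongside conventional
    goodness-of-fit statistics, in-sample and under k-fold
    cross-validation.  Includes seeded synthetic-data generators that
    emulate the sampling structure of sub-location by season livestock
    mortality surveys so the full pipeline can be exercised without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
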