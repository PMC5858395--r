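Package: hdpmeta
Title: Genotype-Count Meta-Analysis and Meta-Prediction for Hypertensive
    Disorders in Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pooled genetic-association meta-analysis of MTHFR genotype
    counts (C677T, A1298C) against hypertensive disorders in pregnancy,
    with fixed- and random-effects (DerSimonian-Laird) pooling on
    standardized total-denominator risk ratios, Hardy-Weinberg screening
    of controls, Egger regression and funnel diagnostics, stratified
    subgroup reporting, and a meta-prediction layer that partitions
    study-level polymorphism summaries over ordinal air-pollution levels
    using AICc-judged binary splits, Tukey-Kramer multiple comparisons,
    nonlinear trend fits, and heat-map density binning. Includes a seeded
    synthetic case-control study generator for end-to-end testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
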