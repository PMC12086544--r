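Package: betabatch
Title: Beta-Regression Batch Correction for DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Batch-effect adjustment for DNA methylation beta-values using
    per-feature beta regression with batch-specific precision. Model
    parameters are estimated by maximum likelihood, a batch-free beta
    distribution is computed for every observation, and values are mapped
    onto it by quantile matching, so adjusted beta-values always stay in
    (0,1). Includes a count-level variant based on beta-binomial regression
    for bisulfite sequencing data, Gaussian ComBat-style baselines on raw
    beta- and M-values, a synthetic bisulfite-data simulator, differential
    methylation testing on M-values, and a type-I-error/power benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    limma
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite,
    withr
Config/testthat/edition: 3
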