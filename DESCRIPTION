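Package: aleomics
Title: Multi-Omics Analysis of Multi-Strain Adaptive Laboratory Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for multi-strain adaptive laboratory
    evolution (ALE) multi-omics experiments: convergence and divergence
    testing of phenotype panels via a pairwise-distance Mann-Whitney
    transform, projection of expression onto a fixed iModulon basis with
    differential-activity testing against a log-normal replicate null,
    growth-correlation screens, jump-specific regulatory trade-off
    detection through PCA and ANCOVA, and screening for associations
    between gained mutations and jump-specific flux or activity changes.
    Includes a synthetic six-strain ALE data generator with planted,
    recoverable signals for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
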