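Package: dtithresh
Title: Stress-Time Cell Death Thresholds for Deep Tissue Injury in Ex Vivo Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pressure-induced cell death in two-channel fluorescence
    cross-sections of ex vivo skeletal muscle and derives stress-time injury
    thresholds. Provides indenter-load to internal-compressive-stress mapping via
    a linear finite-element-calibrated difference model, dead-fiber counting with
    control-derived intensity thresholds and watershed fiber segmentation, a
    permutation test for centralised (indentation-focused) damage patterns,
    count-baseline sample classification, constrained multi-start least-squares
    fitting of four-parameter Boltzmann sigmoid stress-time thresholds, and a
    fully ground-truthed synthetic-data generator for sections and whole
    stress-time studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    EBImage,
    lhs,
    withr,
    jsonlite,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
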