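Package: drcombo
Title: Fixed-Ratio Drug Combination Synergy Analysis and Microarray
    Responder Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting synergy between two compounds combined at a
    fixed dose ratio. Fits four-parameter logistic (4PL) dose-response curves
    by nonlinear least squares, derives equal-potency fixed-ratio designs from
    monotherapy ED50s, constructs the Loewe-additive (Tallarida) theoretical
    dose-response curve for a mixture, computes Combination Indexes, and calls
    synergy by comparing fitted parameters with their 95% confidence
    intervals. Also implements a three-replicate microarray responder
    workflow: fold-change/P thresholding, same-direction replicate filtering,
    probe-to-gene resolution with contradictory-feature removal, and assembly
    of a cross-treatment log2 ratio matrix. Seeded synthetic-data generators
    for plate-reader-like dose-response data (with a tunable Loewe
    interaction index) and multi-feature-per-gene array tables make every
    stage testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
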