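Package: acrlcod
Title: Automated Low-Contrast Object Detectability Scoring for the Large ACR MRI Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of the low-contrast object detectability (LCOD)
    test of the large ACR MRI quality-assurance phantom. Slices 8 to 11 of a
    standard 11-slice acquisition are normalized, the inner contrast disk is
    segmented by histogram thresholding and connected-component analysis, and
    1-D radial intensity profiles cast from the disk centroid are regressed on
    geometric hole-indicator templates plus polynomial nuisance terms. Per-hole
    t-tests with Bonferroni-derived per-slice levels and Benjamini-Hochberg
    false-discovery-rate control yield per-spoke pass/fail decisions, per-slice
    counts, and a 0-40 study total. A synthetic phantom simulator with
    configurable contrast, noise, rotation and bias field makes every stage
    testable without scanner data, and rater-agreement statistics
    (squared-weight kappa, Krippendorff's alpha, one-way ICC, Bland-Altman)
    support validation against human scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
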