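Package: sphingoRT
Title: Retention-Time Extrapolation for Ceramide and Sphingomyelin LC-MS/MS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts liquid chromatography retention times (RTs) of ceramide
    (Cer), sphingomyelin (SM) and hexosylceramide (HexCer) species from their
    molecular structure, anchored on a small set of within-experiment reference
    RTs (internal standards, calibrators or quality controls). Shorthand
    sphingolipid names are parsed into structural descriptors, mass-derived and
    one-hot features feed regularized regression (lasso for Cer, ridge for SM),
    and predictions are organised into mass versus relative elution time (MRET)
    profiles with second-order polynomial trendlines. The predicted RTs support
    the disambiguation of isobaric SM assignments and the flagging of [M+1]
    isotopologue interference in multiple reaction monitoring chromatograms.
    Includes a synthetic gradient/isocratic RT data generator, a learning-curve
    model-selection harness, reference-sensitivity scans, and CSV interfaces
    with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
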