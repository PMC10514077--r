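Package: mzbin
Title: Sliding-Window Feature Construction and Chi-Square Biomarker
    Screening for Mass-Spectrometry Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns variable-length, sparse mass-spectrometry peak lists
    (MZmine-style feature-list exports) into fixed-width feature matrices by
    binning peaks into a sliding m/z window grid and averaging peak height or
    area per window.  Ranks windows by chi-square association with a binary
    phenotype, searches for the minimal top-k feature prefix that maximizes
    validation accuracy over a fixed zoo of ten supervised classifiers, and
    maps selected features back to their original m/z intervals to nominate
    candidate biomarker masses.  Includes a synthetic cohort generator with
    planted discriminative masses and batch effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
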