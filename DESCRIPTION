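Package: morscreen
Title: Distribution-Free Biomarker Screening with the Measure of Relevance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks and selects biomarker candidates in two-sample studies with
    the Measure of Relevance (MoR), a nonparametric, distribution-free score
    that combines a distribution-overlap factor, the biological difference of
    the groups and the pooled dispersion on rank/U-transformed data. Supports
    independent and matched (paired) designs and metric, ordinal and binary
    features. Provides the information chain (features ordered by |MoR|),
    objective and subjective selection criteria (entropy-based stopping rule,
    permutation null distribution, cumulative-information and top-proportion
    cut-offs, and a sample-size-related cut-off), simulation generators for
    calibrating the procedure, a sensitivity/specificity evaluation harness
    with multiple-testing and random-forest baselines, bootstrap confidence
    intervals, and pairwise screening for factors with more than two levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
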