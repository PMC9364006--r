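Package: quadratdesign
Title: Sample-Size Design for Detecting Species Presence in Quadrat Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the minimum number of quadrat samples needed to
    guarantee that the probability of failing to detect a species that is
    present in a surveyed area does not exceed a chosen threshold. Supports
    Poisson and Negative Binomial per-quadrat abundance models, finite or
    effectively infinite area size, and imperfect per-individual
    detectability (false negatives). Provides closed-form non-detection
    probabilities, method-of-moments parameter estimators from count or
    detection data, Monte Carlo validators for the recommended designs, and
    tidy, pipe-friendly interfaces returning tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr,
    yaml
Config/testthat/edition: 3
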