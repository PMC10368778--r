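Package: keyscore
Title: Scoring Naturalistic Keyboard Performance from Keypress Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies naturalistic musical keyboard performance recorded as
    timestamped keypress logs (e.g. from an MRI-compatible MIDI keyboard).
    Performances are encoded as character strings with a simultaneity window
    for chords, melodic accuracy is scored as a Levenshtein ratio against an
    errorless template, and rhythmic accuracy as a percentage deviance of
    onset proportions. Includes an altered-auditory-feedback post-error-slowing
    analysis, a two-component Gaussian latency-mixture fit by EM, a framewise
    displacement motion-exclusion rule, repeated-measures ANOVA helpers, and a
    seedable synthetic-performance simulator used as the test bed for every
    scoring stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
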