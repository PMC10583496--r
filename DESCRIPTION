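Package: speechlex
Title: Lexical Speech Features and Their Test-Retest Reliability in Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts sixteen lexical-semantic features (word count, filler and
    empty-word proportions, part-of-speech proportions, mean log word frequency,
    type-token ratio, Honore statistic, Brunet index, speech and filler rates)
    from transcripts of spontaneous speech, and quantifies their psychometric
    consistency: within-task-type test-retest reliability as Fisher-z-averaged
    Pearson correlations with derangement-resampling null distributions, group
    comparisons of reliability between mild cognitive impairment (MCI) and
    cognitively intact participants, and cross-task intraindividual variability
    of standardized features. Includes a synthetic-cohort generator (feature
    level and transcript level) with controlled inter-task reliability for
    validating the statistical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
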