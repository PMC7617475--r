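Package: tfresponse
Title: Time-Resolved Analysis of Transcription-Factor Induction Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of time-resolved transcription-factor induction
    experiments: kinetic classification of nascent-transcription time courses
    with half-maximal response times, differential chromatin-accessibility
    classification with a binding-motif density statistic, enhancer and
    super-enhancer association analysis, and single-molecule transcriptional
    burst statistics under the two-state telegraph model. Includes a seeded
    synthetic-data generator with known ground truth so that every stage of
    the pipeline can be validated by parameter recovery.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
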