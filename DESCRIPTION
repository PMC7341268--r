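Package: wagr
Title: Welfare Aggregation and Grading for Working Equid Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring and aggregating welfare-indicator survey data
    on working equids. Implements the Welfare Aggregation and Guidance (WAG)
    grading method over Equid Assessment, Research and Scoping (EARS) style
    questionnaire records: per-question welfare levels (good/medium/bad),
    four-question category scores, A-J letter grades, worst-first cumulative
    population grading at a 15% threshold, stratified grade matrices,
    poor-welfare driver ranking, and exact hypergeometric categorical
    description of handler-attitude classes. Includes a seeded synthetic
    population generator emulating a published survey of 2,448 equids in 41
    Nepalese brick kilns, CSV input/output with vocabulary validation, and a
    reproducible reporting pipeline.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
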