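Package: sdohscores
Title: Scoring Tools for the All of Us Social Determinants of Health Survey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relabels and scores participant responses to the All of Us
    Research Program Social Determinants of Health Survey. Ships a
    machine-readable registry of the survey's 14 constructs (80 items) and 30
    literature-informed scoring options; ingests long-format Researcher
    Workbench exports; applies Likert reverse coding and the complete-case
    missing-data contract; reports internal consistency (Cronbach's alpha);
    and generates synthetic survey cohorts with known ground truth so every
    scoring option can be tested without access to controlled data.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
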