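Package: dialtk
Title: Topological and Kinetic Analysis of Task Dialogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotate-and-score analysis of speech-act transcripts from
    two-party task dialogues. Computes kinetic dialogue metrics (vergence,
    the proportion of positively polarized speech acts, and celerity, the
    proportion of decisive ones), encodes dialogues as topological matrices,
    scores graded-prompting cooperation trajectories into occupancy
    probability matrices, fits a small recurrent network forecasting the
    vergence trajectory of an interaction (with rolling re-conditioned and
    counterfactual prompt forecasts), compares groups from summary
    statistics, and generates synthetic annotated dialogues with known
    parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
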