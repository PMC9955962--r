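Package: sentlen
Title: Sentence-Length Perception: Simulation and Signal-Detection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how readers judge sentence length in full-page
    text. Provides a generative simulator for two-alternative "more or fewer
    than 17 words" judgement experiments (word-counting and line-counting
    observers, criterion shifts, lapses, log-normal reaction times) over a
    2 x 2 mixed factorial design, together with the analysis pipeline such
    experiments need: sigmoidal psychometric-function fitting with JND, Weber
    fraction and PSE estimates; signal detection theory d-prime and criterion
    beta under a half-SD z convention with extreme-rate corrections; Monte
    Carlo permutation tests on median differences; lapse and line-counting
    heuristic probes; and binomial inclusion criteria with omega-squared
    based sample-size estimation.
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
    matrixStats,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
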