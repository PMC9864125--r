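Package: canmp
Title: Microplastic Quantification and Dietary Intake Risk for Canned Fish
    Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for market-basket surveys of microplastic contamination in
    canned fish: procedural-blank and spectroscopic verification corrections on
    particle counts, per-brand and grand concentration summaries, particle
    composition analysis (shape, colour, polymer, size class) including
    integer-count reconstruction from published percentages, annual dietary
    intake estimation under configurable consumption scenarios, Monte Carlo
    uncertainty propagation, and the inferential stage (normality checks,
    one-way ANOVA on log-transformed abundances, weight-abundance correlation).
    Ships a reference survey of 33 canned fish products from the Turkish market
    and a synthetic survey generator so every pipeline stage can be exercised
    without laboratory data.
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
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
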