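Package: ejadd
Title: Linking Environmental Justice Indicators to Average Daily Dose Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the EJ-ADD approach: estimating chemical Average Daily
    Dose (ADD) for communities and census tracts, scoring Environmental
    Justice (EJ) indicators (poverty and race/ethnicity) on a 1-10 scale,
    combining chemical mixtures through Relative Potency Factors into an
    Index Chemical Equivalent Dose, stratifying tract-level doses by EJ
    score, and simulating local-scale community exposure scenarios. Includes
    a seeded synthetic census-tract generator so the full pipeline is
    testable without access to national air-toxics or census releases.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
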