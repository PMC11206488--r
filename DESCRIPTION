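Package: npsubstitute
Title: Food Substitution Modelling with the Ofcom Nutrient Profiling Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Scores foods with the UK FSA/Ofcom 2004-05 nutrient profiling
    model under explicit fruit/vegetable/nut content assumptions, models
    same-category substitution of consumed foods by better-scoring
    alternatives under optimistic and realistic scenarios, and estimates
    population-level changes in dietary Ofcom score, calories, saturated
    fat, sodium and total sugars from 24-hour recall surveys using
    bootstrap replicate-weight variance and paired comparisons. Ships a
    seeded synthetic-data generator that emulates the structure of a
    national food-composition database, a branded-product match table
    with market shares, multi-item dietary recalls and survey bootstrap
    weights, so every stage of the pipeline is testable without access
    to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
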