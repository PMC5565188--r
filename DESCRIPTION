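Package: seedfate
Title: Stage-Structured Seed-Fate Simulation for Lizard-Dispersed Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the contribution of a frugivorous disperser to
    plant recruitment from field-style experiments. Reads and validates tabular
    field data (microhabitat use, faeces surveys, cover transects, seed-predation
    trays and seed-sowing stations), estimates replicate-level transition
    probabilities for each recruitment stage (predation survival, seedling
    emergence, seedling survival), and chains them through a stochastic bootstrap
    simulation of seed fate for dispersed versus undispersed seeds. Includes a
    microhabitat-selection index with bootstrap intervals, permutation tests for
    replicate-level proportions, a synthetic field-data generator with known truth
    for parameter-recovery studies, broom-style tidiers, ggplot2 methods and a
    small command-line interface.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
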