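Package: appss
Title: Preference-Performance Association Ranking with Triangular
    Spherical Fuzzy Numbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Multi-criteria decision analysis in which criteria
    preferences and alternative performances are expressed as triangular
    spherical fuzzy numbers (TSFNs), defuzzified with a graded-mean
    integration scoring function, and associated through a bidirectional
    associative memory (BAM) iteration whose fixed point ranks the
    alternatives.  A satisfaction measure compares the BAM ranking with
    an outranking-flow ranking built from pairwise dominance.  Includes
    the complete TSFN algebra (arithmetic, scoring, aggregation, fuzzy
    mean and standard deviation), linguistic scales and count binning,
    the column standardization and min-max normalization pipeline,
    criteria weighting from pairwise linguistic preference matrices, an
    alpha-sensitivity sweep, a random problem generator, and the
    COVID-19 India age-group case study as bundled fixtures.
License: MIT
Encoding: UTF-8
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
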