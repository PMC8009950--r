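Package: nutrieval
Title: Protein Quality, Growth Kinetics and Multi-Criteria Evaluation of Feed Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating candidate animal-feed substrates from
    replicate nutrient-composition panels: amino acid score (AAS), chemical
    score (CS) and essential amino acid index (EAAI) against FAO/WHO and
    whole-egg reference patterns; allometric (power-law) growth-curve fitting
    with weight-gain and specific growth rates; the multi-group comparison
    pipeline (Shapiro-Wilk, Levene, one-way or Welch ANOVA, Duncan's multiple
    range test, Fisher's LSD, Dunnett T3) that produces compact letter
    displays; an analytic hierarchy process (AHP) engine with eigenvector
    priorities, consistency ratios and group aggregation; and rank-based
    radar scoring for cross-category comparison. Ships the published
    composition tables for a semiterrestrial isopod meal, Antarctic krill
    meal and white fish meal as plain-text fixtures, plus synthetic-data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
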