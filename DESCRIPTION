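Package: satzpunkt
Title: Period Disambiguation in Clinical German Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disambiguates the period character in clinical free text, where it
    serves both as abbreviation marker and as sentence delimiter. Provides a
    whitespace tokenizer tuned to clinical German, extraction of candidate
    period sites with their contexts, Dunning log-likelihood collocation
    statistics with a family of scaling functions composed over their power
    set, lexicon and rule based features, corpus-derived abbreviation length
    statistics, and two linear support-vector-machine classifiers (abbreviation
    detection and sentence-boundary detection) with min-max scaling, unit-norm
    preprocessing, cost selection by cross-validation, squared-weight feature
    relevance ranking, and evaluation by micro-averaged F-measure and Cohen's
    kappa. A synthetic clinical-corpus generator with gold labels supports
    training and end-to-end testing without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
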