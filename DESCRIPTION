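Package: seqnam
Title: Interpretable Additive Convolutional Models for Regulatory DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits transparent sequence-to-activity neural models in which
    independent single-filter convolutional units are combined by a single
    linear layer, so that predictions decompose exactly into per-unit
    contributions. Includes filter visualization as position weight
    matrices, unit-importance scores, de novo motif discovery by
    importance-ranked filter extraction, initialization of filters from
    motif-database profiles (with optional freezing), a motif
    distance-dependence (cooperativity) analysis, and a synthetic-data
    generator with planted motifs, GC-matched and dinucleotide-shuffled
    negatives, and linear or pairwise-interaction label rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
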