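Package: cytotaxa
Title: Linking Microbial Taxa to Flow-Cytometry Functional Groups by
    Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates 16S rRNA gene taxon abundances with flow-cytometry
    functional groups (high- and low-nucleic-acid cell counts) in aquatic
    microbial communities. Provides compositional preprocessing (prevalence
    filtering, rarefaction, taxonomic aggregation, centred log-ratio
    transform), a coordinate-descent Lasso and Randomized-Lasso stability
    selection with recursive variable elimination under blocked
    leave-one-group-out and nested cross-validation, Boruta all-relevant
    selection with shadow features, kernel-density cytometric fingerprints
    with per-bin Kendall tau-b maps, rank-correlation and regression
    summaries, and a synthetic-data generator with planted drivers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
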