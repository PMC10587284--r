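Package: fleetdea
Title: Fleet Efficiency, Capacity Utilisation and Productivity Change by
    Data Envelopment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking fishing-fleet production efficiency from
    vessel-year panels. Solves output-oriented variable-returns-to-scale data
    envelopment analysis (DEA) programs to obtain technical efficiency,
    capacity utilisation and unbiased capacity utilisation scores per vessel,
    year and fishing strategy; decomposes Malmquist productivity change into
    efficiency change and technical change with chained cumulative indices,
    giving an estimate of effort creep; and explains capacity-utilisation
    scores in a second stage by exhaustive-subset AIC model selection,
    bootstrap bias-corrected least squares and covariate elasticities. A
    synthetic-fleet generator with known frontier drift, inefficiency and
    covariate effects supports validation against ground truth, and a
    pipeline runner reproduces a full analysis from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
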