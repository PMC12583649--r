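Package: coregulon
Title: Cooperative Regulatory Network Inference and Regulator Influence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cooperative gene regulatory networks from expression
    compendia using a LICORN-style procedure (discretization, co-regulator
    itemset mining, local-program scoring), integrates transcription-factor
    binding and protein-interaction evidence, computes per-sample regulator
    influence scores from regulon contrasts, detects differentially
    influential regulators and differentially expressed genes between
    conditions with Benjamini-Hochberg control, performs hypergeometric
    over-representation analysis, and extracts co-regulatory nodes of
    cooperating regulators.  Includes a synthetic-data generator with
    planted regulatory structure for end-to-end validation.
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
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
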