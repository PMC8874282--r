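Package: herbnet
Title: Network Pharmacology of Multi-Compound Herbal Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, fully testable network-pharmacology pipeline for
    multi-compound herbal extracts: rule-based drug-likeness and ADME gating
    of a compound catalog, multi-source compound-to-target aggregation,
    gene-set enrichment by the accumulative hypergeometric test with
    Benjamini-Hochberg correction and Cohen's-kappa term clustering, and
    content-weighted compound-target-disease network analysis. Includes a
    synthetic-data generator that plants ground truth (known gate-pass
    counts, enriched terms, term families, hub targets) so every stage of
    the pipeline is verifiable without any web-service access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
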