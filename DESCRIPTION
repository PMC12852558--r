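Package: virotriage
Title: Triage and Host Inference for Plant Metavirome Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale analytical stages of a plant
    metatranscriptome virome survey: curation of candidate endogenous and
    exogenous viral elements from ranked similarity hits, open reading frame
    prediction, codon-usage and dinucleotide-composition profiling,
    compositional virus-to-host assignment by Spearman correlation, and
    control-relative transcriptional abundance profiling from per-library
    quantification tables. Includes seeded generators of synthetic contigs,
    hit tables and expression matrices so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
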