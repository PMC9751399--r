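Package: metresist
Title: Metabolome-Linked Methotrexate Resistance Screening for Leukemia Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for linking cell-line metabolomes to
    drug resistance. Implements drug-induced fold-change screening of NMR
    metabolite panels with exact Wilcoxon signed-rank tests against unity,
    metabolite- and gene-versus-phenotype Pearson correlation screens,
    continuous-phenotype gene set enrichment analysis with gene-set
    permutation, hypergeometric metabolite-set over-representation, IC50/LD50
    and AUC summaries of dose-time viability surfaces, doubling-time
    estimation, and Bliss-independence synergy scoring of fixed-ratio drug
    combinations via the log2 ratio of additive to combination LD50. Includes
    a synthetic-data generator that plants recoverable treatment effects,
    phenotype correlations, enriched gene sets and synergy offsets so the
    whole pipeline is testable without external data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
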