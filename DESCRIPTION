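Package: lcenet
Title: lncRNA-Associated Competing Endogenous RNA Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Construction and biomarker analysis of lncRNA-associated
    competing endogenous RNA (ceRNA) networks. Builds a global
    lncRNA-miRNA-mRNA network from miRNA-target interaction catalogs with a
    hypergeometric test on shared miRNA regulators, derives context-specific
    networks from differential expression and positive lncRNA-mRNA
    co-expression, and screens lncRNA/miRNA biomarkers and key regulatory
    triplets with the NSM (number of shared miRNAs) and NSR (number of
    single-line regulated RNAs) network statistics. Includes ROC, Kaplan-Meier
    survival and over-representation evaluation, and a seeded synthetic-data
    generator with planted ground truth so every pipeline stage can be
    validated without external downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
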