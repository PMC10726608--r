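Package: pancankit
Title: Pan-Cancer Multi-Omic Cohort Analysis and Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for integrative pan-cancer analysis of multi-layer tumor
    cohorts shaped like TCGA: a cohort data model aligning expression
    (log2(TPM+1)), clinical annotation, tumor mutational burden, microsatellite
    instability, immune-cell ratios, single-sample enrichment immune scores and
    promoter methylation; a hand-written statistics core (rank tests, BH,
    Kaplan-Meier, log-rank, Efron Cox regression, ROC/AUC, single-sample and
    preranked gene-set enrichment, hypergeometric over-representation); the
    pan-cancer and cancer-type-specific analyses built on it (tumor-normal
    boxplot tables, metric-correlation radar tables, immune heatmap grids,
    Cox forest tables, DEG + GSEA, co-expression panels, survival splits,
    gene-term networks); a seeded synthetic-cohort generator with planted,
    recorded effects for offline testing; ggplot2 rendering; and a thin
    command-line dispatcher.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    pROC,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
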