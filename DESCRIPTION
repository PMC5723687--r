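Package: inflammage
Title: Inflammatory Biologic Age and Downstream Omics Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates inflammatory biologic age from a panel of circulating
    inflammatory biomarkers with the Klemera-Doubal method, computes the
    difference between biologic and chronologic age (delta age), and carries
    that quantity through a family-aware downstream analysis: a per-feature
    linear mixed-model association scan (transcriptome- or epigenome-wide)
    with Bonferroni control, a weighted expression score with Cox survival
    follow-up, Fisher/FDR pathway and overlap enrichment, a greedy
    dense-module search on a protein-protein interaction network, and a
    permutation-based integration of methylation with expression including a
    CpG-adjusted attenuation analysis. A synthetic-cohort generator with the
    statistical structure the analysis assumes makes every stage testable
    without access to controlled cohort data.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
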