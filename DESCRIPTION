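Package: guideomics
Title: Metabolome-Guided Multi-Omics Analysis of Gut Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated analysis of paired metagenomic,
    metatranscriptomic, metaproteomic and meta-metabolomic profiles from
    case-control gut microbiome cohorts. Implements guide-layer selection by
    PERMANOVA against diagnosis and confounders, metabolite-guided
    differential analysis (Kruskal-Wallis with Dunn post hoc,
    Benjamini-Hochberg correction), KEGG-ortholog retrieval for significant
    compounds by name-pattern matching over a reaction universe, paired
    gene-versus-transcript differential testing, genus-resolved functional
    expression with per-function Shannon diversity, and a community-wide
    bipartite KO-metabolite network with betweenness-centrality analysis of
    metabolite subnetworks. Ships a synthetic study generator with recorded
    planted truth so the full pipeline is testable end to end.
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
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
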