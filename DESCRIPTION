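Package: cervotype
Title: Paired Luminal and Tissue-Adherent Cervicovaginal Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-omics analysis workflow for
    paired cervicovaginal luminal and tissue-adherent microbiome samples:
    rule-based community-state typing of both sites (L1-L5 / T1-T5), paired
    shift and concordance analysis, alpha diversity and Mann-Whitney
    differential abundance on log2[CP1K+1] abundances, shared-nearest-neighbor
    graph construction with Jaccard pruning and Louvain community detection,
    per-taxon correlation-ranked gene set enrichment (preranked GSEA) against
    host gene expression, negative-binomial differential expression with
    module clustering and hypergeometric set enrichment, and protein/cytokine
    group statistics with limit-of-detection handling. Ships a synthetic
    paired multi-omics generator with planted ground truth so the whole
    pipeline is testable end to end without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    edgeR,
    fgsea,
    biomformat,
    withr,
    optparse
Config/testthat/edition: 3
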