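Package: scregwalk
Title: Regulatory Mechanism Reconstruction from Single-Cell Multi-Omics
    with Heterogeneous Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles heterogeneous multilayer networks from single-cell
    multi-omics data (a transcription-factor layer, a peak co-accessibility
    layer inferred from scATAC, a transcriptional-regulation layer inferred
    from scRNA, and optional extra omics layers such as methylation), joined
    by bipartite inter-layer links from motif scanning and genomic
    proximity. Random walks with restart over the multilayer yield ranked
    transcription-factor targets, binding regions, gene regulatory regions,
    weighted gene regulatory networks with per-TF regulons, and Louvain gene
    communities. Includes evaluation utilities (ranking overlap, one-sided
    Fisher enrichment, F1 on region sets, community gene-set enrichment,
    Spearman comparison of networks) and a synthetic unpaired multi-omics
    generator with planted regulatory cascades and matching ground truth.
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
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    Matrix,
    methods,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
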