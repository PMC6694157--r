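Package: pathext
Title: Pathway Extension on Multi-Omics Weighted Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Integrates DNA methylation and gene expression data to re-weight a
    gene-gene interaction network per phenotype, using per-gene principal
    components of CpG beta values merged with expression and a sparse canonical
    correlation analysis (penalized matrix decomposition) edge weight. Curated
    pathways are extended with high-relevance neighbour genes found by a
    truncated absorbing random walk (limited kWalks) on each phenotype-specific
    network, and altered pathways are identified by hypergeometric
    over-representation analysis and phenotype-permutation gene set enrichment
    analysis over the extended gene lists. Includes a synthetic multi-omics
    generator with planted bridge genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    fgsea,
    optparse,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
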