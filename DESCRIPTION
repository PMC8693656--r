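Package: progmark
Title: Signature-Score-Based Marker Discovery in Progenitor Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resolves heterogeneity hidden inside a flow-defined progenitor
    population from transcriptome data. Derives population signature gene
    sets from bulk RNA-seq of two sorted populations, scores single cells
    by the sum of per-gene Z-scores over a signature, stratifies cells into
    score tertiles, extracts genes upregulated in the lineage-committed
    stratum by a Wilcoxon rank-sum test with Benjamini-Hochberg correction,
    filters candidates to surface-molecule-encoding genes, transfers gene
    sets across species, and validates candidate subsets with a weighted
    Kolmogorov-Smirnov gene-set enrichment statistic under a gene-label
    permutation null. Ships a negative-binomial synthetic-data generator
    that plants a committed subpopulation, lineage-restricted program genes
    and a co-regulated surface marker, so the whole discovery loop is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
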