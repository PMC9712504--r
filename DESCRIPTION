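Package: cephatlas
Title: Statistical Building Blocks for a Cephalopod Brain Cell-Type Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the bespoke computational stages
    behind a droplet single-cell atlas of the octopus paralarval brain:
    evidence-guided extension of gene 3' ends from long-read isoform ends,
    mRNA cleavage sites and short-read coverage; batch-aware droplet and
    gene quality-control filtering; cluster-stability scoring by subsampling
    and Jaccard matching; the tau cell-type-specificity index with rank-based
    gene-family enrichment; a neighbor-joining cell-type taxonomy with
    gene-resampling bootstrap support; Fisher's exact gene-family enrichment
    over marker tables; and marker-composition statistics. A synthetic-data
    module generates negative-binomial droplet counts with planted cell
    types, marker phenotypes, batches and gene families, plus a toy genome
    fixture with known true 3' ends, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
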