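Package: gwasnet
Title: Systems-Level Analysis of GWAS Data with Weighted Gene
    Coexpression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts SNP-level genome-wide association P-values into
    LD-aware gene-wide P-values (proxy clustering, nearest-gene
    assignment, SNP-count adjustment), builds a weighted gene
    coexpression network (soft-thresholded adjacency, topological
    overlap, average-linkage module detection, SVD module eigengenes)
    over the nominally significant GWAS gene set using
    phenotype-labelled expression data, computes per-gene module
    membership, gene significance and intramodular connectivity,
    assesses module gene-set enrichment against random-network and
    random-gene-set permutation nulls, and compares replication rates
    in a second GWAS for genes prioritized by connectivity versus
    association P-value. Ships a synthetic-data generator that plants
    coexpression modules, phenotype coupling, associated genes, LD
    blocks and a pathway gene set so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
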