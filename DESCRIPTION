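Package: lrrminer
Title: Genome-Wide Mining of NBS-LRR and LRR-RLK Immune Receptor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide identification and
    characterization of plant LRR-containing immune receptor genes. Candidate
    NBS-LRR and LRR-RLK catalogs are built from Pfam-style domain hits (HMMER3
    domtblout), NBS-LRR candidates are classified as TIR-type (TNL) or
    coiled-coil-type (CNL) with a sliding-window heptad-propensity scorer,
    gene clusters are called on genome coordinates with a 200-kb rule,
    duplicated genes are grouped into multigene families by global affine-gap
    alignment under coverage/identity criteria, and gene sets are
    characterized by pairwise identity/similarity, progressive multiple
    alignment, and neighbor-joining phylogenies with bootstrap support. A
    synthetic-genome simulator with a ground-truth ledger makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
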