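Package: panlineage
Title: Comparative Genomics and Lineage Delineation for Giant-Virus Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to delineate lineages within families of large double-stranded
    DNA viruses (exemplified by the Marseilleviridae) from annotated genomes.
    Implements the full comparative pipeline: GenBank I/O and descriptive genome
    statistics, all-vs-all Smith-Waterman protein alignment with k-mer
    prefiltering, reciprocal-best-hit orthology and paralogous-family detection,
    one-way and two-way average amino-acid identity (AAI), greedy protein
    clustering into clusters of orthologous groups with pan-/core-genome
    accumulation curves, phyletic presence/absence profiles with Pearson-distance
    hierarchical clustering, core-gene concatenated phylogeny and an SPR-distance
    supertree, and an AAI-threshold lineage-assignment rule with a multi-line
    evidence report. A calibrated synthetic genome-family simulator with full
    truth tables makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    igraph,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    rtracklayer
Config/testthat/edition: 3
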