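Package: amoebahgt
Title: Detecting Gene Exchange Between Amoebal Genomes and Giant Viruses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting putative nucleotide sequence
    exchange between an Acanthamoeba host genome and the ORFomes of giant
    viruses. Provides seeded synthetic draft genomes with implanted viral
    genes and machine-readable truth tables; six-frame ORF prediction and
    assembly statistics; Smith-Waterman protein similarity search with
    Karlin-Altschul e-values; best-hit taxonomic labeling and the
    viral-candidate filter cascade (length, scaffold context, merged-database
    re-screen); sliding-window "rhizome" gene mosaicism scanning;
    neighbor-joining trees with rule-based transfer-direction inference and
    Fitch ancestral reconstruction; synteny conservation of viral-gene
    scaffolds across genomes; and Cytoscape-ready exchange-network export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    igraph,
    jsonlite,
    withr,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
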