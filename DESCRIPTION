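Package: symtyper
Title: Deep Amplicon Sequencing Detection and Quantification of Symbiont Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of dominant and background symbiont
    types (and within-type haplotypes) from deep amplicon sequencing of the
    ribosomal ITS locus, as used for Symbiodinium communities in reef corals.
    Provides a mock-community read simulator for dilution-series designs,
    barcode demultiplexing and primer/quality/length filtering, 100%-identity
    read clustering with histogram-based reference selection, reference
    mapping with unique-best-hit semantics, type annotation via a curated
    panel with diagnostic-SNP tie-breaking, pruning of reference libraries
    using known-dominant samples, normalization of mapped read counts to
    percentages, detection-limit estimation from pure samples, Goodman-Kruskal
    gamma rank correlation with permutation tests, bootstrap confidence
    intervals, intra-genomic variant inference from cross-sample haplotype
    correlations, and minimum-spanning haplotype networks that count indel
    runs as single mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
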