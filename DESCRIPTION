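Package: pirnakit
Title: Small RNA Analysis of piRNA-Mediated Regulation and Its
    Pharmacological Reversal
Version: 0.1.0
Authors@R:
    person("pirnakit", "maintainers", email = "pirnakit@example.org",
           role = c("aut", "cre"))
Description: Tools for four-group small RNA sequencing studies of
    PIWI-interacting RNA (piRNA) regulation and its reversal by a
    counteracting treatment: read filtering and hierarchical reference
    assignment with at most one mismatch, tags-per-million normalisation,
    MA-plot random-sampling differential expression on pooled libraries
    with Benjamini-Hochberg and Storey q-values, 5'-anchored
    complementarity target prediction against mRNA and miRNA, reversal /
    overlap / fold-change-correlation integration, common-substring motif
    extraction, hypergeometric over-representation analysis, a
    planted-truth synthetic study generator, and a command line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
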