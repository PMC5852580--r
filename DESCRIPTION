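Package: famevol
Title: Gene Family Duplication, Molecular Evolution, and Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for characterizing plant gene families from
    genomic coordinates and coding/protein sequences: duplicate-pair calling
    from pairwise protein alignment (identity and coverage thresholds),
    tandem versus segmental classification and gene-cluster detection from
    chromosome coordinates, Nei-Gojobori Ka/Ks estimation with Jukes-Cantor
    correction, selection-mode and divergence-time inference, neighbor-joining
    phylogeny with bootstrap supports and clade-based class assignment,
    protein physicochemical properties (length, molecular weight, isoelectric
    point), and qPCR relative-expression analysis by the 2^-ddCt method with
    one-way ANOVA and Tukey comparisons. Includes synthetic-data generators
    that plant duplication structure, divergence targets, and expression
    fold-changes so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    multcomp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
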