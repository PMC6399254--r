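Package: nicksv
Title: Structural Variant Detection from Nick-Labelled Optical Genome Maps
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for calling large (>2 kb) structural variants from
    optical genome mapping data. Provides in silico digestion of reference
    sequences at nicking-endonuclease motifs with instrument-resolution
    label merging, dynamic-programming alignment of single-molecule and
    contig label maps to reference maps with permutation-calibrated
    confidence scores, likelihood-ratio indel calling from inter-label
    distances under a five-hypothesis diploid model (molecule-reference,
    contig-reference and molecule-contig-reference modes), split-alignment
    detection of inversions, duplications and translocations with a
    support-versus-rejection molecule score, genome region complexity
    classification with permutation enrichment tests, cohort-level
    population-structure summaries (SV occurrence matrix, sharing
    fractions, neighbour-joining tree, PCA, size ANOVA, trio concordance),
    and a synthetic optical-map simulator with configurable label error
    models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
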