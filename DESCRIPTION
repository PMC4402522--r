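Package: splicearch
Title: 3' Splice-Site Architecture, Single-Strandedness and Alternative
    Polyadenylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the 3' splice-site organization of exon cohorts:
    AG exclusion zone (AGEZ) length, branch-point prediction with a
    weight-matrix scorer, polypyrimidine-tract (PPT) detection anchored at
    the best branch point, and intrinsic splice-site strength from
    frequency-matrix models. Computes equilibrium base-pair probabilities
    and per-position unpaired probabilities (PU) under a pair-additive
    energy model via McCaskill-style inside-outside recursions, and
    positional delta-PU statistics with Wilcoxon-Mann-Whitney tests.
    Classifies differentially used exons by transcript position and
    categorizes alternative polyadenylation (APA) events into tandem
    3'UTR, intronic and alternative-3'ss APA with proximal/distal shift
    tallies. Includes a deterministic synthetic-cohort generator with
    planted sequence, structure and correlation effects so that every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
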