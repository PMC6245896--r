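Package: anuramp
Title: Targeted Amplicon Discovery of Anuran Antimicrobial Peptides
Version: 0.1.0
Authors@R:
    person("anuramp", "developers", email = "anuramp@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for parallel discovery of anuran
    antimicrobial peptides (AMPs) by targeted amplicon sequencing.
    Designs family-specific degenerate forward primers from alignments of
    conserved signal-peptide coding regions, simulates and processes
    Ion-Torrent-like amplicon reads (quality trimming, demultiplexing,
    greedy overlap-layout-consensus assembly, read-support filtering,
    re-mapping and stringent re-assembly of polymorphic contigs), screens
    contigs for AMP precursors with a position-specific profile scan and a
    translated Smith-Waterman search against a known-AMP database,
    annotates precursor open reading frames (signal peptide, acidic
    propeptide, Lys-Arg cleavage, C-terminal amidation, rana-box motif,
    novelty tiers, eight-class grouping) and computes physicochemical
    descriptors (net charge, mean hydrophobicity on a consensus scale,
    average molecular weight) for the mature peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
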