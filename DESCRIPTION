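Package: methkit
Title: Downstream Analysis of Whole-Genome Bisulfite Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Context-resolved analysis of per-cytosine bisulfite methylation
    calls in plant genomes: CG/CHG/CHH context classification, genome-wide
    methylation summaries and windowed tracks, metagene profiles over gene and
    transposable-element bodies with 2-kb flanks, a rule-based differentially
    methylated region (DMR) caller with chi-square testing and recursive
    segmentation, hurdle and negative-binomial regression of expression on
    regional methylated-cytosine counts with tenfold cross-validated Q2,
    positional classification of long non-coding RNAs, and 24-nt siRNA
    association statistics. Includes a deterministic two-tissue methylome
    simulator with planted DMRs and a full truth set so every stage can be
    validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
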