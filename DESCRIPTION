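Package: tinyintron
Title: Characterization of Tiny Spliceosomal Introns and Their snRNA
    Pairing Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts spliceosomal introns from a genome (FASTA) and its
    annotation (GFF3) in a strand-aware way and computes the cohort
    statistics used to characterize extremely short (15-16 nt) introns:
    length-class shares, terminal dinucleotides, splice-site position
    frequency matrices with information content, branchpoint adenosine
    calls, lariat loop/tail geometry, AU content, unique-sequence tallies,
    intron-per-gene summaries, gene-length comparisons and 5-prime
    positional bias.  Implements an antiparallel RNA-RNA duplex model of
    the spliceosomal active site (Watson-Crick, G-U wobble and
    non-canonical U-U pairs; branch helix with a bulged branchpoint
    adenosine) against the U1, U2 and U6 snRNA recognition motifs, and
    ships a seedable synthetic-genome simulator with a machine-readable
    truth table so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
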