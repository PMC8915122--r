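Package: srnasig
Title: Small RNA Locus Discovery and Biogenesis Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers small-RNA-producing loci from genome alignments as
    coverage islands and characterizes their biogenesis pathway. Computes the
    piRNA ping-pong signature (z-score of 10-nt 5'-5' overlaps between
    opposite-strand reads), the Dicer signature (same-length pairs overlapping
    by length minus two, i.e. 2-nt 3' overhangs), Zucchini-type phasing
    statistics (3'-to-next-5' distance histograms and positional uridine
    profiles), and first-nucleotide bias. Curates candidate miRNA hairpins by
    duplex-overhang geometry, 5' processing precision and star-strand support,
    and scans precursors for short-loop perfect-stem hairpins. Classifies
    piRNA loci by strand bias, genomic context, size and repeat-peak
    structure, and performs a genome-wide scan for endogenous siRNA loci
    (strand-ratio bins, per-size overlap z-score matrices, 21/21-nt
    19-nt-overlap duplex counts, phased-run detection). Ships a deterministic
    synthetic-data generator that emulates every locus class with truth
    labels, so the whole pipeline is testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
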