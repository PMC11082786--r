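Package: psiseq
Title: Pseudouridine Site Calling from CMC Reverse-Transcription Stop Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pseudouridine (Psi) sites from strand-specific single-base
    3'-end (reverse-transcription stop) coverage of CMC-treated and mock-treated
    sequencing libraries. Extracts RT-stop coordinates from alignments, filters
    putative strong-stop peaks, tests each peak against a Poisson background
    fitted in an exon-constrained window, controls the false-discovery rate with
    the Benjamini-Hochberg procedure, and calls single-nucleotide Psi sites as
    CMC-specific, T-adjacent stops. Includes normalized peak-height comparison
    between samples, guide-RNA target motif scanning with contiguous-match
    scoring, and a fully synthetic ground-truthed data simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
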