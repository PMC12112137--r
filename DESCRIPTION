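Package: arrascan
Title: Detection and Classification of Antisense-Promoter Architectures in
    the rpmH-dnaA Intergenic Region of Bacillus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for the arrA antisense-promoter
    architecture found between rpmH and dnaA in Bacillus chromosomes. Reads
    annotated genomes (GenBank flat files or FASTA plus GFF3), extracts the
    rpmH-dnaA intergenic region on the strand antisense to dnaA with exact
    coordinate provenance, scans it for SigA-type -10/-35 promoter elements
    under mismatch and spacer budgets, detects DnaA boxes on both
    orientations by consensus similarity, and classifies each locus into the
    Group I-IV spacing architectures (16/2, 14/4, 11/7 bp gaps between the
    -10 and its two flanking DnaA boxes, or promoterless). Includes a seeded
    synthetic-locus generator with planted architectures and spurious-hit
    masking, transcript-length arithmetic for run-off and terminator-bounded
    transcripts, an anchor alignment on the conserved DnaA box, and a
    scan/simulate/evaluate/align pipeline with TSV, BED and FASTA outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
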