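Package: orgweave
Title: Organelle-to-Nuclear Transfer Detection and Long-Read Assembly Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies organelle-to-nuclear DNA transfers
    (NUMTs, NUPTs, ambiguous NUM/PTs and complex tandem NUMPTs) from
    organelle-versus-nuclear alignment hits, validates insertion junctions
    with long-read alignments, and provides the surrounding assembly-curation
    toolkit: Shannon-entropy low-complexity contig screening, read-depth
    outlier detection of organelle-derived contigs, telomere motif scanning
    with telomere-to-telomere completeness calls, tandem-repeat and rDNA
    array profiling (unit length, copy number, 5S/35S linkage), annotation
    hygiene filters (transposon-term majority rule, unsupported-gene removal,
    repeat-library relabeling, pseudogene flagging by alignment-length
    fraction), and contig-to-scaffold relationship classification with
    windowed self-alignment density screening for candidate centromeres.
    A deterministic synthetic-genome generator plants every feature class
    with a machine-readable truth table so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    optparse
SystemRequirements: NCBI BLAST+ (optional, for FASTA-input alignment)
Config/testthat/edition: 3
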