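Package: klfscout
Title: Discovery of SP/KLF-Family Zinc-Finger Genes and Pseudogenes in Genomic Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational discovery of new members of the SP/KLF
    family of C2H2 zinc-finger transcription factors. Detects zinc fingers by a
    configurable spacing grammar (CX4CX12HX3HX7CX4CX12HX3HX7CX2CX12HX3H),
    classifies finger signatures against SP/KLF, EGR-like and WT1-like spacing
    patterns, reports conservation of DNA-contact arginines and their acidic
    partners, scans N-terminal regions for the [YC]x[GASTDNPE][QH] repeat motif
    (density, tandem runs, position-frequency matrix), locates candidate loci by
    conserved flanking anchor genes, performs six-frame translated locus scans
    with splice-aware gene-model assembly and premature-stop pseudogene calling,
    and infers duplication histories (local gene duplication versus
    retrotransposition) with anchor-based alignment, distance matrices,
    neighbor-joining trees and monophyly tests. A synthetic-genome simulator
    plants KLF-like families, decoys and event histories with exact truth labels
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
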