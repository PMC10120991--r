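Package: crossseq
Title: Genome-Wide CRISPR Off-Target Calling from ssDNA-Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR editing events (nuclease cleavage, base-editor
    conversion, prime-editor insertion) genome-wide from aligned
    single-stranded-DNA enrichment sequencing reads. Builds strand-resolved
    read-end pileups, scores candidate cleavage sites with a depth-normalized
    cleavage-signal statistic, subtracts a no-guide control to remove
    endogenous ssDNA background, quantifies editor-specific signatures
    (base conversion within the editing window, programmed insertion at the
    nick), and annotates candidates by bulge-aware alignment to the guide
    spacer. A bundled simulator generates aligned reads with planted on- and
    off-target signals so every stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
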