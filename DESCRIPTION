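Package: riboUORF
Title: Detection and Differential Translation Analysis of Upstream Open
    Reading Frames from Ribosome Profiling Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers upstream open reading frames (uORFs) in transcript
    leader sequences of protein-coding genes, counts ribosome protected
    fragments (RPFs) on main ORFs and uORFs by inferred P-site position,
    normalizes libraries with median-of-ratios size factors, and ranks
    stimulus-dependent changes in main ORF-to-uORF occupancy ratios to
    nominate translation-regulatory uORFs. Includes a fully synthetic
    test-world generator (genome FASTA, Gencode-style GTF, simulated RPF
    alignments with planted condition-dependent effects) and a command-line
    entry point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
biocViews: RiboSeq, Sequencing, Annotation, Translation,
    DifferentialExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
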