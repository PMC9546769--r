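Package: umi5p
Title: Simulation, Extraction and Quality Control of 5' UMI Reads from
    Template-Switching scRNA-seq Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for plate-based single-cell RNA-seq protocols whose
    template-switching oligo (TSO) carries a unique molecular identifier
    (UMI) and a short spacer.  Provides a ground-truth read simulator
    (genome, annotation, paired FASTQ, alignments, variants); motif-grammar
    UMI extraction from read 1 or read 2 (rescue of intra-TSO tagmentation
    events); detection, quantification and filtering of strand-invasion
    artifacts by matching the UMI against the strand-aware upstream genomic
    context; per-gene UMI deduplication into molecule counts with an
    edit-distance diagnostic; per-cell SNP benchmarking against an exome
    reference; and gene-detection saturation, resampled gene-diversity and
    Kendall-tau correlation statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
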