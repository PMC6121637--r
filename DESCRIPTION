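Package: methexpr
Title: Methylome-Transcriptome Analysis for Two-Condition Whole-Genome
    Bisulfite Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative DNA-methylome and transcriptome analysis
    of a two-condition, replicated whole-genome bisulfite sequencing (WGBS)
    design. Provides strand-aware CG/CHG/CHH context classification,
    per-cytosine methylation levels with bisulfite non-conversion correction
    estimated from an unmethylated spike-in control, genome-wide context
    summaries and level histograms, metagene methylation profiles over gene
    bodies and 2-kb flanks, a beta-binomial differential-methylation caller
    with dispersion shrinkage and region merging, FPKM computation with a
    negative-binomial two-group differential-expression test, and an
    integration layer that cross-classifies differentially methylated
    regions, differentially expressed genes, and transposable elements.
    Includes a self-contained synthetic-data generator (genome, annotations,
    cytosine reports, count matrix, spike-in) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
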