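Package: methage
Title: Age-Resolved DNA Methylome Analysis from Bisulfite Cytosine Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing age-structured whole-genome bisulfite
    sequencing (WGBS) data in species with large, transposon-rich genomes
    such as conifers. Starting from per-cytosine methylation count files
    (Bismark-style cytosine reports), the package computes context
    (CG/CHG/CHH) and trinucleotide sub-context methylation landscapes,
    gene and transposable-element metaprofiles, intron-length-stratified
    profiles, fixed-window differentially methylated regions (DMRs) with
    Fisher exact tests and Benjamini-Hochberg FDR control, replicate-noise
    exclusion and cross-comparison consensus of age DMRs, short time-series
    model-profile clustering of methylation trajectories, and
    methylation-expression linkage including age-marker segment
    correlation. A fully configurable synthetic methylome generator with
    planted ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
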