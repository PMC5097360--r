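Package: nexusPeaks
Title: Barcode-Aware Processing and qfrag-Based Peak Calling for
    ChIP-nexus and ChIP-exo Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of ChIP-nexus and ChIP-exo experiments:
    extraction of random (UMI) and fixed barcodes from raw FASTQ reads with
    adapter clipping, reduction of mapped reads to strand-aware 5'-end hits,
    selective PCR-duplicate removal using random barcodes together with
    duplication-level statistics (IM/IMIB/IMUB), unbiased estimation of the
    protected-region width from the qfrag-length distribution corrected by a
    strand-swapped pseudo-control, and qfrag-coverage peak calling with
    Poisson significance testing and Benjamini-Hochberg FDR control. A
    ground-truthed read simulator is included so that every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'HitSet-methods.R'
    'dedup.R'
    'fastq-preprocess.R'
    'mapped-reads.R'
    'nexusPeaks-package.R'
    'qfrag.R'
    'peaks.R'
    'simulate.R'
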