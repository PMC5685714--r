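Package: plasmaCNA
Title: Ultra-Low-Pass Whole-Genome Copy-Number Screening for Cell-Free DNA
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide somatic copy-number screening from ultra-low-pass
    whole-genome sequencing (0.005-1.3x) of cell-free DNA. Implements binned
    read counting with mapping-quality and duplicate filters, GC-bias
    correction, panel-of-normals log2 copy-ratio normalization with
    coverage-adaptive bin sizing, circular binary segmentation with
    permutation-based change-point testing, a least-squares tumor-fraction
    statistic (LSS) with simulation-based calibration and an integer
    copy-number grid fit, focal/arm-level/deep-deletion event calling,
    fraction-of-genome-altered scoring, an in-silico dilution and
    downsampling simulator, and genome-wide profile concordance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
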