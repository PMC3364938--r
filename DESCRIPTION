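Package: GenomicAssociations
Title: Spatial Association Statistics for Pairs of Genomic Interval Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Statistical tests for the spatial association between two sets
    of genomic intervals (a query set evaluated against a fixed reference):
    the relative-distance test (Kolmogorov-Smirnov and permutation ECDF-area
    variants with a signed correlation-like measure), the scaled absolute
    minimal-distance test, the projection (binomial) test for points in
    intervals, and the Jaccard overlap test with spacing-preserving
    permutation. Results are reported per chromosome and genome-wide, in
    both query/reference orientations, with optional restriction to
    investigator-defined genomic subsets. Includes a synthetic feature-set
    generator with known spatial relationships for calibration and power
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
biocViews: StatisticalMethod, GenomeAnnotation, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
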