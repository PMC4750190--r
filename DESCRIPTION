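Package: hmboundary
Title: Genomic and Epigenomic Characterization of Hypomethylated Block Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the boundaries of large hypomethylated
    blocks (HMBs) such as those observed in colon cancer. The package builds
    fixed-length boundary regions around block edges, samples GC-matched
    control regions, scans position weight matrices with exact null p-values
    to build motif-count feature matrices, discriminates boundaries from
    control regions with random forests (permutation importance), tests motif
    and chromatin-modification-enzyme enrichment with Fisher's exact test,
    summarizes positional bias of motif occurrences, computes boundary-aligned
    ChIP-signal metaprofiles and CTCF-stratified comparisons, and measures
    intra-block Hi-C interaction strength and proximity of topologically
    associating domain boundaries to block boundaries. A synthetic-data
    generator with planted structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    GenomicRanges,
    rtracklayer,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
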