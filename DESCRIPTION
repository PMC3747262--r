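Package: tilemeth
Title: Region-Level Differential Methylation Analysis for MeDIP Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls ~1 kb differentially methylated regions (DMRs) from two-channel
    MeDIP tiling-microarray data by combining per-probe empirical-Bayes moderated
    t-statistics with a region-level Wilcoxon rank-sum enrichment test under
    Benjamini-Hochberg false-discovery-rate control, and correlates region
    methylation with continuous plasma phenotypes. Includes quantile normalization
    of log2 bound/input ratios, replicate averaging, annotation of called regions
    against gene models (nearest gene, signed TSS distance, promoter membership)
    and regulatory-element interval tracks, statistics for targeted bisulfite
    pyrosequencing validation, and a seeded synthetic-data generator that
    reproduces the statistical structure of a two-group tiling-array study for
    power and false-discovery calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
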