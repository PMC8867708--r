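Package: adaptscan
Title: Landscape-Genomics Selection Scans and Polygenic Scores for
    Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for detecting range-wide local adaptation
    from SNP genotypes of strongly structured populations, built around the
    workflow used in landscape genomics of pond- and stream-breeding
    amphibians. Provides iterative missingness filtering, Weir-Cockerham
    F-statistics with bias-corrected bootstrap intervals, genotype PCA and
    K-means/BIC clustering, environmental variable pruning and distance
    matrices, per-locus selection scans (PCA-regression outliers, FLK,
    covariance-standardized XtX with pseudo-observed-dataset calibration, and
    two genetic-environment association procedures), consensus overlap with
    permutation nulls, missingness-normalized additive polygenic scores with
    binomial-logit GLMMs and random-subset null distributions, nearest-gene
    annotation with BEDTools-closest semantics, and a synthetic-data generator
    with planted adaptive loci for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    geosphere,
    ggplot2,
    IRanges,
    jsonlite,
    lme4,
    phangorn,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
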