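Package: hicnb
Title: Negative Binomial Background Correction for Hi-C and Capture Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies statistically significant chromatin interactions in
    Hi-C and capture Hi-C contact maps. Read counts of bin pairs are modelled
    with a negative binomial background whose mean is the product of learned
    per-bin bias factors and a cubic-in-log-distance decay with a constant
    background-ligation floor, smoothed by a soft-maximum so the likelihood is
    differentiable. All parameters are fitted by maximum likelihood (ADAM) in
    multiple rounds that mask putative real interactions and replace their
    counts by model expectations when computing bin totals. Includes a
    three-class extension for capture Hi-C baits, a generative simulator with
    spike-in loops for calibration and recovery experiments, and
    interval-overlap enrichment statistics for evaluating calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    data.table,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
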