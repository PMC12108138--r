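Package: stabprs
Title: Stability-Selected Polygenic Risk Scores via Iterative Bootstrap Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of cohort-specific polygenic risk
    scores (PRS) for quantitative traits by an iterative bootstrap procedure:
    variant and sample quality control, linkage-disequilibrium pruning,
    principal component analysis with Tracy-Widom selection of significant
    components, per-variant association scans, clumping-and-thresholding PRS
    derivation with empirical permutation p-values, frequency-based variant
    aggregation across resampling iterations, incremental-R2 candidate
    selection with empirical bootstrap p-values, hold-out validation, and
    association of the final score with secondary phenotypes.  Includes a
    synthetic-cohort generator with known causal architecture (linkage
    blocks, population structure, imputation quality scores, missingness)
    so the whole pipeline can be exercised without access to private
    genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    yaml,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
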