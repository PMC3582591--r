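Package: pcfseg
Title: Piecewise Constant Fitting for Copy Number Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of DNA copy number data by penalized least squares
    piecewise constant fitting (PCF). Provides exact single-sample
    segmentation by dynamic programming, joint multi-sample segmentation with
    common breakpoints, allele-specific segmentation of paired logR/BAF SNP
    array tracks, and a fast heuristic based on high-pass filter candidate
    breakpoints. Includes Winsorization of outliers against a median-filter
    trend, robust residual scale estimation for penalty scaling,
    missing-value imputation, threshold-based aberration calling, penalty
    diagnostics, and simulation tools (null Gaussian and contaminated-normal
    profiles, planted aberrations, paired SNP tracks) together with
    brute-force enumeration oracles for validating the dynamic programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
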