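Package: epiaccel
Title: Epigenetic Age Acceleration from DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating DNA methylation (DNAm) age with a penalized
    regression clock, deconvolving blood immune-cell composition from CpG beta
    values by reference-based non-negative least squares, and computing the
    universal, intrinsic (IEAA) and extrinsic (EEAA) measures of epigenetic age
    acceleration, including the Klemera-Doubal composite biological age that
    underlies EEAA. Includes a synthetic methylation cohort generator with
    known ground truth (intrinsic age offsets, cell-composition trajectories,
    group and sex effects, multi-dataset replicates), Illumina-style beta-value
    preprocessing (intensity-to-beta conversion, gold-standard quantile
    calibration, probe blacklisting with constant-mean imputation), group
    comparison tests, Stouffer and inverse-variance fixed-effects
    meta-analysis, and a config-driven end-to-end pipeline with a robustness
    re-analysis mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    splines,
    glmnet,
    pracma,
    tibble,
    dplyr,
    readr,
    rlang,
    yaml,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
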