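Package: pacar
Title: Phenotype-Aware Components Analysis for Case-Specific Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrastive dimensionality reduction for case/control omics data.
    Implements Phenotype-Aware Components Analysis (PACA), which estimates the
    axes of variation shared between a case matrix and a control matrix by
    canonical correlation analysis in the sample space, removes the minimal
    number of shared axes needed to expose case-specific structure, and returns
    principal components of the residual as putative phenotypic subtypes.
    Includes a randomized variant for datasets with more samples than features,
    PCA and contrastive-PCA baselines, a generative simulator for calibration
    and power experiments, and permutation-based significance testing of the
    recovered structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
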