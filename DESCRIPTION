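Package: echowall
Title: Carotid Wall Echolucency: Gray-Scale Median Quantification and
    Determinant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies carotid artery wall echolucency as the gray-scale
    median (GSM) of B-mode ultrasound regions of interest, with per-image
    black/white calibration, the darkest-of-thickest plaque selection rule,
    left/right intima-media averaging, and scan-rescan reproducibility
    statistics. Identifies independent determinants of plaque-GSM and IM-GSM
    via a 200-iteration split-sample stability-selection procedure with
    sequential partial R-squared decomposition, and stratifies atherosclerotic
    burden risk through quartile odds-ratio grids and ROC AUC comparison.
    A synthetic-cohort module emulates a five-country high-cardiovascular-risk
    cohort, scan-rescan pairs, and speckled wall images so every stage of the
    pipeline is testable against known ground truth.
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
    pROC,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
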