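Package: fingerchem
Title: Chemometric Analysis of HPLC-DAD Chromatographic Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating medicinal-plant species from HPLC-DAD
    chromatographic fingerprints and for locating the chromatographic peaks
    associated with antioxidant activity. Provides a synthetic-data generator
    with known ground truth (Gaussian peak libraries, drifting baselines,
    duplicate injections, antioxidant assay panels), a preprocessing pipeline
    (blank subtraction, replicate-reproducibility gating, consolidation,
    iterative fill-peaks baseline correction, window cropping), similarity and
    cluster-validation measures (Pearson correlation distance, Ward linkage,
    cophenetic correlation, Hopkins clustering tendency), a composite relative
    antioxidant capacity index (RACI) in z-score-mean and first-principal-
    component forms, and from-scratch NIPALS-PLS and OPLS regression with
    leave-one-out cross-validation, fit metrics and regression-coefficient
    marker assignment against retention-time standards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
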