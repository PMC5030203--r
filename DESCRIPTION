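Package: mbfpet
Title: Myocardial Blood Flow Quantification from Dynamic Cardiac PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying myocardial blood flow (MBF) from dynamic
    cardiac PET. Implements voxelwise and region-level fitting of the
    one-tissue compartment model with left- and right-ventricular spillover
    terms via the basis function method with noise-equivalent-count weighted
    least squares; calibration, background subtraction, dispersion and delay
    correction of continuously sampled arterial blood curves; image-derived
    input-function (IDIF) partial-volume and scale corrections with nested
    F-test model comparison; estimation of the generalized Renkin-Crone
    extraction model by weighted orthogonal distance regression; and
    method-agreement statistics (Deming regression, Lin concordance,
    Bland-Altman with reproducibility coefficient). A synthetic-data module
    generates ground-truth input functions, a voxelized cardiac phantom with
    known kinetics, and simulated arterial-monitor readings so the whole
    pipeline is testable end to end.
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
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
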