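Package: ventavoid
Title: 4DCT-Ventilation Functional Avoidance Virtual Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing 4DCT-ventilation functional
    avoidance radiotherapy trials. Computes per-voxel lung ventilation maps
    from paired exhale/inhale CT volumes and a displacement vector field via
    the Hounsfield-unit density-change model, quantifies spatial ventilation
    heterogeneity (lung-thirds percent ventilation, ipsilateral/contralateral
    ratio, coefficient of variation) with ROC-based trial-eligibility
    thresholding, auto-segments a functional-avoid structure, evaluates plans
    with standard dose-volume and dose-function (structure-based and
    image-based) metrics, and orchestrates the full virtual trial on digital
    thorax phantom cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
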