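Package: boldcvr
Title: Voxel-Wise BOLD Cerebrovascular Reactivity Mapping and
    False-Negative Task Activation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses combined BOLD cerebrovascular
    reactivity (CVR) and task-evoked fMRI studies under normocapnic and
    hypercapnic CO2 baselines. Provides a synthetic 4D phantom generator
    with known regional ground truth, voxel-wise CVR mapping (temporal
    smoothing, hemodynamic lag estimation, least-squares regression on
    the end-tidal CO2 trace), a mass-univariate task GLM with a
    double-gamma haemodynamic response function, region-of-interest
    summaries with paired condition tests, and identification of
    false-negative activation voxels provoked by impaired vasodilatory
    reserve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
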