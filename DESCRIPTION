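Package: venoasl
Title: Arterial Spin Labelling Perfusion Quantification and Venous
    Outflow Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cerebral blood flow (CBF) from single inflow-time
    pseudo-continuous arterial spin labelling (pCASL) difference images and
    jointly fits voxel-wise CBF and bolus arrival time (BAT) from multi
    inflow-time pulsed ASL (PASL) series using the Buxton general kinetic
    model. Includes physiological calibration (arterial oxygen content,
    hematocrit- and oxygen-saturation-dependent blood T1), ghost-free
    background noise estimation with reliable-voxel masking, region-of-
    interest construction including a high-signal sagittal-sinus ROI
    defined by a percentile threshold on the single inflow-time CBF map,
    a digital perfusion phantom and cohort simulator, and a statistical
    stage with normality-gated group comparisons, age- and sex-adjustment,
    stratified Benjamini-Hochberg false-discovery-rate correction, and
    covariate-adjusted cognition regressions. Designed for studies of
    venous ASL signal in anemic populations such as sickle cell anemia.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
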