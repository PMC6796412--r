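Package: kbplan
Title: Knowledge-Based Automated SBRT Plan Parameter Prediction for Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for knowledge-based stereotactic body radiotherapy (SBRT)
    planning in non-small-cell lung cancer. Extracts anatomical geometry
    features from voxelized thoracic structure masks (PTV, lung, heart and
    optional serial organs), screens them by Spearman rank correlation against
    historical plan parameters, trains support-vector-regression models that
    predict patient-specific VMAT arc start/stop gantry angles and achievable
    lung dose (mean lung dose, V10, V20), and assembles a complete
    plan-parameter specification with template organ-at-risk constraints.
    Includes dose-volume-histogram evaluation (Dx, Vx, ICRU-83 homogeneity
    index, Paddick conformity index), paired Wilcoxon plan-cohort comparison,
    and a synthetic thorax cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
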