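Package: tiltmap
Title: Lesion Mapping of Tilt-Dependent Body-Axis Perception Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking whole-body-tilt-induced distortion of
    perceived body-axis orientation to brain lesion topography in stroke
    cohorts. Computes subjective-visual-body-axis (SVBA) errors and
    tilt-dependent errors (TDE) from trial-level psychophysics data, applies
    lesion-side sign conventions and a control-referenced abnormality cut-off,
    builds patient-by-voxel damage matrices from binary NIfTI lesion masks,
    produces lesion-overlap and subtraction maps, performs voxel-wise Bayesian
    lesion-deficit inference with Jeffreys-Zellner-Siow (JZS) Bayes-factor
    two-sample t-tests, and evaluates brain-behaviour associations with
    Pearson and partial correlations plus correlation Bayes factors. Includes
    a synthetic lesion-cohort generator so the full pipeline can be exercised
    and validated without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
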