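Package: foveametry
Title: Foveal Morphometry of Infant OCT B-Scans with a Difference-of-Gaussians Pit Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying foveal development in preterm infants from
    hand-held optical coherence tomography (OCT) B-scans. Provides B-scan
    preprocessing (Bruch membrane detection, A-scan flattening, internal
    limiting membrane segmentation, micrometre scaling), an asymmetric
    difference-of-Gaussians model of the foveal contour fitted per side by
    bounded nonlinear least squares with analytic derivatives to third order,
    derivative-based foveal metrics (width, depth, area, central foveal
    thickness, steepest wall slope, parafoveal thickness, rim positions via
    the third-derivative rim-edge rule), longitudinal linear mixed-effects
    modelling of metric trajectories against postmenstrual age, retinopathy
    of prematurity status, gestational age and birthweight, and a synthetic
    data generator (profiles, B-scan images, longitudinal cohorts) with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite,
    tiff,
    yaml,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr
Config/testthat/edition: 3
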