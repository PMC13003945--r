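Package: djpls
Title: Drop-Jump Biomechanics and Partial Least Squares Determinant Analysis
Version: 0.1.0
Authors@R: person("DJ", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of drop-jump trials: zero-lag Butterworth
    filtering with residual-analysis cutoff selection, ground-contact and
    take-off detection from vertical ground reaction force, eccentric and
    concentric phase segmentation at the centre-of-mass minimum, a rigid-link
    segment model with Cardan joint angles and bottom-up inverse dynamics,
    phase-tagged kinetic and kinematic features (reactive strength index,
    vertical stiffness, impulse ratio, joint work), and a filtered,
    cross-validated partial least squares regression with variable importance
    in projection scores. Includes a dynamically consistent synthetic
    drop-jump generator and a latent-structure tabular generator so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
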