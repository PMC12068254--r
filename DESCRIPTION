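Package: wallmotion
Title: Point-Level Assessment of Aneurysm Wall Characteristics from
    Pulsatile Wall-Motion Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Tools for point-level classification of cerebral aneurysm wall
    regions (thin-walled versus hyperplastic-remodeling) from 3D wall-point
    trajectories such as those extracted from time-resolved CT angiography.
    Includes a synthetic pulsatile-motion cohort generator with controllable
    class separability and patient heterogeneity, kinematic feature
    extraction (speed, acceleration, planar smoothness-of-motion angles), a
    CNN-LSTM regression network with temporal attention trained with a
    composite loss combining a prediction-error term, a patient-invariance
    term and an unlabeled-separation term, leave-one-patient-out
    cross-validation with method ablations, and distributional heterogeneity
    diagnostics (two-sample Kolmogorov-Smirnov, Levene, dynamic time warping,
    1-D Wasserstein).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
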