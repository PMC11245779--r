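Package: cyclokin
Title: Hip-Knee Cyclogram Coordination Metrics and One-Dimensional
    Statistical Parametric Mapping for Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for inter-joint (hip-knee) coordination of
    human gait from sagittal-plane joint-angle time series.  Segments gait
    cycles at initial-contact events, time-normalizes them to a fixed
    percent-gait-cycle grid, and computes cyclogram (angle-angle)
    coordination variables: joint ranges of motion, the angular coefficient
    of correspondence (a circular-statistics coherence of cyclogram segment
    directions across cycles), the sum of squared distances between
    cyclogram shapes, extremal cyclogram points, and between-speed
    adaptation ratios.  Provides one-dimensional statistical parametric
    mapping (two-sample and paired t continua with random-field-theory
    thresholds, cluster inference, and a permutation twin), amplitude
    normalization for temporal comparisons, and the scalar cohort
    statistics used in clinical gait studies (normality-gated two-group and
    repeated-measures comparisons with Bonferroni or Conover post hocs).
    Includes a synthetic gait-kinematics generator with normative hip and
    knee templates so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
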