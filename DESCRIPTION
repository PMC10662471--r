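Package: sescom
Title: Center-of-Mass Estimation with Statically Equivalent Serial Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the three-dimensional human center of mass (CoM) from
    joint angles using the statically equivalent serial chain (SESC)
    technique. Provides branched kinematic body models of graded complexity
    (7 to 19 degrees of freedom), forward kinematics and weighted-segment CoM
    computation, least-squares identification of the subject-specific SESC
    parameter vector from static postures and force-plate center-of-pressure
    (CoP) readings, preprocessing of raw angle and CoP time series
    (zero-phase low-pass filtering, resampling, static-posture detection),
    synthetic-cohort generation with known ground truth, and agreement
    evaluation (RMS error, correlations, Bland-Altman limits of agreement
    with fixed and proportional bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
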