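Package: magposture
Title: Posture Estimation for Dynamic-Soaring Birds from Tri-Axial Magnetometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers yaw and roll angles of dynamic-soaring seabirds from
    calibrated tri-axial magnetometer time series under a zero-pitch
    assumption. Implements the passive intrinsic yaw-pitch-roll rotation
    model, the two-branch arccosine yaw inversion with branch
    disambiguation over dynamic-soaring windows, interpolation of roll
    across magnetic north/south headings, hard-/soft-iron ellipsoid
    calibration, a geomagnetic reference-field module with a bundled
    degree-12 spherical-harmonic model, a synthetic-data simulator
    (soaring trajectories, compass swings, pitch-sensitivity error grids),
    and validation utilities (accelerometer control roll, wrap-safe binned
    errors, soaring-cycle counting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
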