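Package: gaitIMU
Title: Running Gait Analysis from a Single Foot-Mounted Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatiotemporal and kinetic running gait parameters from
    a single foot-mounted inertial measurement unit (tri-axial accelerometer
    and gyroscope). Implements quaternion orientation tracking with a Mahony
    proportional-integral complementary filter, adaptive mid-swing stride
    segmentation, fused kinematic/kinetic detection of initial and terminal
    contact (MFD-GED) alongside the conventional angular-velocity baseline
    (AVGS), zero-velocity-update (ZUPT) drift-corrected stride reconstruction,
    a spring-mass (SLIP) sinusoidal model of vertical ground reaction force,
    and the agreement statistics (Bland-Altman, ICC, paired tests) used to
    validate wearable gait systems. A synthetic foot-trajectory simulator with
    exact ground-truth events and parameters supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
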