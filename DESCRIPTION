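Package: imugait
Title: Foot-Mounted IMU Gait Analysis with Zero-Velocity-Aided Inertial Navigation
Version: 0.1.0
Authors@R:
    person("Ad", "Hoc", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating spatio-temporal gait parameters (stride
    length, stride time, stance/swing time, clearance, speed, cadence) from
    foot-mounted inertial measurement unit recordings.  Implements strapdown
    integration with an error-state Kalman filter corrected by zero-velocity
    updates during stance, peak-detection gait-event extraction from raw
    angular velocity, and agreement evaluation against a reference stride
    table (linear regression, Bland-Altman limits of agreement, and a
    K-means/silhouette screen for left-right inconsistency).  A synthetic
    gait generator produces ground-truth foot trajectories, converts them to
    ideal IMU signals by inverse strapdown, and injects vendor-style sensor
    artifacts (noise, bias, scale error, range clipping, packet loss,
    timestamp jitter) for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
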