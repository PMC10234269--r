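Package: gaitfpe
Title: Foot Placement Errors and Push-Off Kinetics in Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study anterior-posterior (AP) foot placement control and
    its correction by ankle push-off during treadmill walking. Provides a
    synthetic gait generator with full ground truth (center-of-mass states,
    foot placement errors, kinetic feedback gains, center-of-pressure
    "butterfly" trajectories), gait event detection from the combined
    center-of-pressure signal, step segmentation and two-window time
    normalization, phase-dependent linear regression of foot placement on
    center-of-mass states, correlation of the resulting foot placement errors
    with push-off kinetic time series over the subsequent stride, and group
    level inference via Fisher r-to-z aggregation with permutation-based
    one-dimensional cluster tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
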