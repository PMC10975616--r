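Package: bottleneckgait
Title: Kinematic Analysis of Individual Pedestrians Crossing a Bottleneck
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-run kinematic analysis of individual pedestrians walking
    through a narrow aperture (bottleneck): crossing-point localisation on the
    centre-of-mass trajectory, running-mean speed and smoothed-acceleration
    profiles, five-way classification of deceleration behaviour, shoulder
    rotation with 3-sigma onset and maximum-amplitude detection, heel-strike
    detection with stance-foot assignment, and cross-run aggregation (crossing
    offset law, exponential amplitude-versus-ratio fit with a Tukey-grid
    critical point, correlation matrices). Includes a synthetic gait-trajectory
    generator with a ground-truth channel so every detector can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
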