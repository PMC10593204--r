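Package: heartpace
Title: Constant Input-Sensitivity Feedback Design and Simulation for
    Heart-Rate Control During Treadmill Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing linear time-invariant feedback compensators
    that regulate heart rate during treadmill exercise by commanding belt
    speed. Implements a pole-cancelling synthesis that renders the input
    sensitivity function exactly constant over all frequencies for any stable
    strictly proper plant, with closed forms for the first-order and
    two-phase (second-order) heart-rate response models, reference prefilter
    shaping to a critically damped target response, a seeded closed-loop
    simulator with synthetic participants (heart-rate-variability-like
    disturbance, measurement noise, actuator saturation), and the paired
    outcome statistics used to compare controllers: root-mean-square tracking
    error and average control-signal power, with Lilliefors normality
    screening and one-sided paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
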