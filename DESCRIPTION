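Package: orpose
Title: Operating-Room Staff Activity from Pose Tracks and Workload Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra-operative staff activity from multi-person 2D
    pose detections recorded by ceiling cameras in the operating room, and
    relates it to perceived workload and job satisfaction. Provides a
    two-stage confidence-split pose tracker, a three-zone "active at the
    operating table" classifier with a movement-speed veto, phase-level
    activity/movement/interaction percentages, scoring and rank-based
    analysis (Friedman, Nemenyi, Kendall's W) for a seven-domain Surgery
    Task Load Index extended with job satisfaction, hospital-schedule
    deviation metrics, and seeded synthetic-scene generators with known
    ground truth so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
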