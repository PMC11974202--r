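Package: movediary
Title: Reliability and Accelerometer-Based Evaluation of 24-h Movement
    Behavior Time-Use Diaries in Early Childhood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate parent-reported 24-h movement behavior
    time-use diaries for children aged 0-4 years. Classifies diary entries
    into physical activity, sedentary behavior and sleep from activity
    category, intensity, posture, age group and motor milestones; expresses
    daily time use as a 3-part composition via isometric log-ratio pivot
    coordinates; estimates single-day intraclass correlations and the
    Spearman-Brown minimum number of reporting days over a grid of daily
    hour-coverage and day-count inclusion criteria; converts raw triaxial
    acceleration into 5-s epoch ENMO and MAD metrics with autocalibration
    and non-wear screening; aligns diary entries with epoch series; and
    tests an enumerated ledger of direction and similarity hypotheses with
    linear mixed models. A seeded synthetic-data generator emulates both
    diary and accelerometer streams with known ground truth so the whole
    pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    emmeans,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
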