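Package: pitchcoach
Title: Offline Analysis Core for Voice Pitch Training Exercises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for gender-affirming voice pitch training
    software: fundamental-frequency estimation by normalized autocorrelation
    with pure-tone validation, target-matching exercise models (constant,
    chanting, stair, human-curve) with their success and phase-advance rules,
    the per-repetition exercise-error metric, and the session-level
    performance and usability statistics pipeline (SUS and IMI scoring,
    paired half-comparisons with Benjamini-Hochberg correction,
    repeated-measures ANOVA with Holm-Sidak post hoc tests). A deterministic
    synthetic-audio and simulated-user module makes every component testable
    without human recordings.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
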