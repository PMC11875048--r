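Package: setshiftr
Title: Simulation and Analysis of a Cross-Modal Attentional Set-Shifting Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hardware-free, seeded discrete-event engine for a head-fixed
    two-alternative forced-choice attentional set-shifting task in which mice
    report decisions about compound whisker and odor stimuli by licking left
    or right spouts. Implements the full staged training curriculum
    (habituation, shaping, simple and compound discrimination), the trial
    state machine with bias-corrected reward scheduling, performance-triggered
    serial rule switches (intradimensional shifts, reversals, and
    extradimensional shifts), reinforcement-learning mouse agents that
    reproduce acquisition, perseveration, side bias, anticipatory licking and
    satiety, and the standard behavioral analytics: moving-window accuracy,
    trials to criterion, switch-aligned performance, and the modality by
    congruency by timing factorial analysis.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    car,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
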