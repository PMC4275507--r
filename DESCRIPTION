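Package: hfcoach
Title: Automated Education and Coaching Engine for Heart Failure Self-Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable engine for an automated education-and-coaching
    program for heart-failure self-care. Scores behavior and knowledge
    questionnaires, places patients in a knowledge-by-behavior matrix,
    gates tailored education, runs goal-based weekly coaching with
    diary evaluation and motivational feedback, detects adherence
    (personal goals reached for two consecutive weeks) and relapse at
    two-month follow-up, and replays per-patient event logs through the
    coaching state machine. Includes a stochastic cohort simulator, a
    deterministic 123-patient study fixture, journey-table reporting,
    an eligibility screener, and a command-line interface.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
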