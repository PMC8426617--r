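Package: kiosksim
Title: Headless Simulator and Analysis Toolkit for Touchscreen Cognitive
    Task Batteries in Nonhuman Primates
Version: 0.1.0
Authors@R:
    person("Kiosksim", "Developers", email = "kiosksim@example.org",
           role = c("aut", "cre"))
Description: Simulates, without any hardware, the cognitive-task machinery of
    cage-mounted touchscreen kiosk stations used to train and profile rhesus
    monkeys: a combinatorial multidimensional object ("Quaddle") stimulus
    space with CIELAB-equidistant color palettes, seeded generators and
    discrete-event state machines for Touch-Hold-Release shaping, visual
    search, and flexible feature-reward learning tasks, synthetic behavioral
    agents (a set-size reaction-time responder and a feature-based
    reinforcement learner), and the standard behavioral statistics: per-set-
    size reaction-time regression (slope = set-size effect, intercept =
    baseline speed of processing), sliding-window trials-to-criterion,
    plateau accuracy, learning curves, and weekly aggregation. Session logs
    are written incrementally as JSON-Lines so interrupted runs lose no
    completed trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
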