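Package: luckydoor
Title: Simulation and Group Analysis of a Two-Choice Reward Task with EEG Band Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying value-based decision-making with the two-door
    probabilistic reward ("Lucky Door") task and simultaneous EEG. Provides a
    formal model of the task (deck payoff structure, expected value
    arithmetic, stochastic outcome generation), synthetic cohort and epoched
    EEG generators with configurable group effects, the Win-Stay behavioral
    statistic and robust group regression models, a channel-space EEG
    preprocessing chain (resampling, band filtering, artifact rejection,
    trial averaging, baseline correction), cluster-based permutation scalp
    statistics with false discovery rate control, and neurobehavioral
    interaction models, tied together in a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
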