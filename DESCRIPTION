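Package: nightwatch
Title: Event-Driven Nighttime Monitoring for Ambient Assisted Living
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-process event-condition-action (ECA) rule engine with
    FIFO tables and publish/subscribe channels, together with three
    nighttime-monitoring services for ambient assisted living: bed
    presence/absence detection from windowed load-cell statistics with
    Otsu-calibrated thresholds, online first-order mining of room-transition
    probabilities and inter-event transition times, and a C4.5 decision-tree
    classifier of early-night behaviour from sliding-window event features.
    A semi-Markov night simulator with full ground truth makes every service
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
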