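Package: limbkin
Title: Triggered Limb-Acceleration Recordings: Protocols, Signal
    Conditioning and Kinematic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless pipeline for wearable three-axis accelerometer
    studies of ballistic limb movements (e.g. cued thumb abduction).
    Implements a sample/event/block recording model with a plain-text
    three-file on-disk format, a stimulation-protocol engine (free
    running, acoustic stimulation and external trigger modes), signal
    conditioning (automatic offset calibration with explicit gravity
    handling, first-order high-pass filtering, magnitude computation),
    and kinematic analysis: trapezoidal integration of acceleration to
    velocity and displacement over user-selected segments, per-event
    peak acceleration, per-block summary statistics and percent change
    across blocks.  A synthetic-sensor module generates static gravity
    recordings under rotation, biphasic ballistic movement events and
    multi-block motor-practice experiments so the whole pipeline is
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
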