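Package: tomomotion
Title: Respiratory Motion Tracking and Dose Delivery Simulation for Helical
    Tomotherapy QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intrafraction respiratory
    motion management on helical tomotherapy deliveries. Generates stochastic
    three-dimensional Lujan (sin^2n) breathing traces with hysteresis, baseline
    drift and a chest-surrogate channel; emulates surrogate-correlation tumor
    tracking driven by sparse intra-rotation kV position fixes and a continuous
    LED surrogate stream; quantifies tracking error (delta RMS and percentile
    statistics, cumulative error curves, kV/breathing aliasing diagnostics);
    accumulates time-resolved dose for static, uncompensated and
    motion-compensated delivery scenarios with a parametric helical beam model;
    and compares dose distributions by global gamma index (TG-218 style
    criteria), median dose difference and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
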