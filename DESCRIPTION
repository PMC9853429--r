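Package: trailgait
Title: Wearable-Sensor Trail Running Biomechanics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of trail-running footwear studies instrumented
    with foot-mounted inertial measurement units (dual-range accelerometers and
    a gyroscope), plantar-pressure insoles, and a GPS/heart-rate watch. Fuses
    low-g and high-g accelerometer streams, detects synchronization hops,
    segments running strides from the jerk-squared magnitude, estimates
    per-stride running speed by gravity-corrected double integration with
    zero-velocity updates and linear de-drifting, extracts per-stride peak
    acceleration, peak jerk, medial-lateral acceleration range and peak foot
    eversion velocity, computes heel/toe contact area and peak pressures per
    stance phase, segments the trail into uphill/top/downhill sections from GPS,
    and contrasts two shoe-closure configurations with linear mixed-effects
    models and estimated marginal means. Includes a synthetic-study generator
    with known ground truth so the full pipeline is testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    emmeans,
    geosphere,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    signal,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
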