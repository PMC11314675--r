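Package: stridemap
Title: Stride-Level Activity Recognition and Iterative Path-Network
    Construction from Wearable Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-stage wearable-sensing pipeline. The first
    stage segments thigh and shank inertial recordings into individual
    strides via peak detection on the thigh pitch angle, extracts
    per-stride inclination statistics, and classifies each stride as
    level walking, stair ascent, or stair descent with support vector
    machine or decision tree models under leave-one-subject-out and
    leave-one-trial-out protocols. The second stage georeferences
    classified steps by interpolating GPS fixes, and grows a geographic
    path network incrementally: new traces are simplified, matched
    against stored paths by distance and heading, split at match
    boundaries, merged by merge-count-weighted averaging, and joined
    through crossings that form a bidirectional graph. Synthetic gait
    and GPS-trace generators over known ground-truth networks support
    end-to-end validation, and map quality is scored by geometric and
    topological correctness against a reference network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    rpart,
    geosphere,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
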