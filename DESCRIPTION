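Package: routemem
Title: Collective Route Memory Analysis for Homing Pigeon GPS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying collective route memory in homing pigeons
    from GPS homing tracks. Implements track preprocessing (stationary-point
    speed filtering, homing-segment trimming, joined-flight detection and
    within-pair split truncation), route-fidelity metrics (mean nearest
    neighbour distance to baseline routes, second-order mean nearest
    neighbour distance, homing efficiency index), multimember linear
    mixed-effects models fitted by REML with fractional-membership random
    effects, Wald tests and planned contrasts via releveling, and a synthetic
    flight generator emulating a paired-release training and memory-testing
    design with differential forgetting across pair members.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
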