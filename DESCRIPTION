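Package: equibone
Title: Coupled Bone Adaptation and Microdamage Dynamics in Racehorse
    Subchondral Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of subchondral bone
    adaptation, fatigue microdamage accumulation and osteoclast-mediated
    repair in the lateral condyle of the equine third metacarpal bone.
    Bone volume fraction evolves by strain-energy-regulated formation and
    resorption (Hill-type mechanoregulation on the specific surface), and
    damage evolves as a fatigue life fraction with stiffness-adjusted
    per-cycle damage and remodelling-coupled repair. The package provides
    the model laws, an event-terminating simulator for piecewise-constant
    loading schedules, translation of phased training programmes into
    loading schedules with per-speed damage attribution, calibration of
    activity and fatigue parameters to cross-sectional bone volume
    fraction data and fracture times, Latin-hypercube PRCC and Sobol
    global sensitivity analysis, and a synthetic-data generator emulating
    the structure of the calibration data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
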