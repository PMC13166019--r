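Package: insolecop
Title: Sensor Number and Placement Optimization for Center-of-Pressure
    Estimation on Instrumented Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how many plantar-pressure sensors an instrumented
    insole needs, and where, to track the center of pressure (CoP) during
    walking. Implements barycentric CoP reconstruction from a 16-cell pressure
    array, physiological gait-cycle segmentation (force-threshold and
    heel-to-toe roll-over criteria), exhaustive evaluation of all 65,535
    sensor subsets against the full-array reference trajectory, and the
    downstream marginal-gain, selection-frequency, cross-performance and
    spatial error-map analyses. A seeded synthetic plantar-pressure generator
    makes the whole pipeline testable without human gait recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
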