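Package: rpmsim
Title: Partial-Gravity Simulation and Planning for Random Positioning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator, planner and diagnostics toolkit for ground-based
    partial-gravity experiments on Random Positioning Machines (RPMs).
    Implements the software paradigm, in which the residence-time
    distribution of the gravity vector is uniform over a prolate spheroid
    with one focal point at the rotation centre, yielding a tunable mean
    gravity factor between 0 and 1 g via the spheroid eccentricity; and the
    hardware paradigm, in which a centrifuge mounted on an RPM supplies a
    centripetal g-level on top of the RPM's near-weightless baseline.
    Provides two-gimbal rigid-body kinematics, seeded trajectory
    generation, the eccentricity-to-mean-gravity quadrature and its
    inverse, centrifuge settings solvers with residual-g and g-gradient
    analysis, equi-gravity sample placement, and equal-area orientation
    density maps on the unit sphere with uniformity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
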