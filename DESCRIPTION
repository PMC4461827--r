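Package: gazekin
Title: Kinematic Planning and Simulation of 3-D Head-Free Gaze Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plans and simulates coordinated three-dimensional eye-head gaze
    shifts toward visual targets. Given a target (on a flat screen or as a
    retinal error), initial eye-in-head and head-in-space orientations, and
    eye-head coordination parameters, the planner solves a static kinematic
    model that foveates the target while driving the final eye-in-head
    orientation into Listing's plane and the final head orientation onto the
    zero-torsion Fick surface, with the saccade pre-compensating a predicted
    vestibulo-ocular reflex. Trajectories are obtained by temporal
    discretization with an ideal online VOR, and experiment drivers sweep
    target grids to analyze torsional orientation ranges ("bow-tie"
    distributions) under different coordination strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
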