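Package: canalith
Title: Mechanistic Simulation of Canalith Repositioning Maneuvers in a
    Semicircular Canal Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the transport of a canalith (free-floating otoconial
    debris) along the slender duct of a semicircular canal during
    parametrized Semont repositioning maneuvers for benign paroxysmal
    positional vertigo.  Implements overdamped Stokes settling of a single
    spherical particle in a rotating canal frame with absorbing duct ends,
    the dynamic-similarity scaling between a five-fold scaled bench model
    and the human labyrinth, rigid-body lever-arm kinematics with
    centrifugal and tangential inertial terms, a seeded synthetic generator
    for manually operated maneuvers, and the experimental protocol layer:
    critical resting-time scans, wall-drag calibration, replication of the
    full experimental configuration grid, and a clinical maneuver
    recommendation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
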