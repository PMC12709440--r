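Package: mtmigrate
Title: Whole-Cell Simulation of Actin-Microtubule Crosstalk Driven Cell
    Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic two-dimensional whole-cell model of mesenchymal cell
    migration driven by actin-microtubule crosstalk. The cell and nuclear
    boundaries are semiflexible bead-spring loops, microtubules are dynamic
    bead-spring filaments anchored at a mobile centrosome and subject to
    two-state dynamic instability, and cortical/perinuclear dynein motors
    pull on passing filaments. Growing microtubule tips deliver local
    protrusion signals to the membrane and shrinking tips deliver local
    contraction signals, which together polarize the cell and drive
    migration. Includes confined environments (pillar obstacle parks,
    Y-junction and multi-channel microfluidic devices with chemotactic bias)
    and a trajectory analysis toolkit (time-averaged and windowed mean-square
    displacement exponents, directional persistence length, polarity angle
    statistics, cell morphology, and channel-choice statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
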