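Package: supercoilex
Title: Supercoiling-Driven Chromatin Loop Extrusion Through a Frictional
    Cohesin Ring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Brownian-dynamics simulator and analysis toolkit
    for transcription-driven chromatin loop extrusion through a
    pseudo-topologically bound cohesin ring. Implements a torsionally stiff
    circular bead-spring fiber (10 nm / 400 bp beads with periaxial virtual
    beads carrying the twist degree of freedom), a constant-speed negative
    supercoiling motor with moving torsional nicks, a 14-bead cohesin ring
    whose friction with the fiber is tunable, and overdamped Langevin
    dynamics with per-bead drag. Topology analytics include discretized
    Gauss-integral writhe, material-frame twist, linking-number budgets,
    supercoiling density, loop-size and extrusion-rate estimators,
    persistence length, and Hi-C-like contact maps. A continuum
    moving-boundary (Stefan-type) model of supercoiling diffusion coupled to
    energy-gradient cohesin motion can be solved numerically and fitted to
    simulated loop-size and linking-number trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
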