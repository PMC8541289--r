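Package: acoustofocus
Title: Acoustophoretic Focusing Analysis for Bulk Acoustic Wave Resonators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models transverse acoustophoretic focusing of microparticles and
    cells in a half-wavelength bulk acoustic wave (BAW) resonator. Provides the
    closed-form radiation-force physics (acoustic contrast factor, Stokes drag,
    critical particle diameter, transverse particle path), estimation of the
    acoustic energy density and pressure amplitude from tracked particle
    trajectories, a limiting-velocity acoustic-streaming model with a
    finite-difference Stokes solve of the boundary-driven flow in the channel
    cross-section, an overdamped particle-trajectory simulator for
    focusing-efficiency studies, and a synthetic trajectory generator that
    emulates time-lapse particle-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
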