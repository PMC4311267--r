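Package: speedred
Title: Speed-Coefficient Model Reduction for Biochemical Reaction Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Systematic reduction of biochemical ordinary-differential-
    equation models by fast-slow asymptotics. Variables are ranked by speed
    coefficients (the absolute diagonal Jacobian entries evaluated along a
    representative solution); the variable that is fastest at its slowest is
    eliminated by a zeroth- or first-order quasi-steady-state approximation,
    and the procedure iterates, recording oscillation metrics of every
    reduced variant. Includes symbolic affine decomposition and substitution
    chains, stiff simulation under piecewise-constant stimulus protocols,
    Hopf-bifurcation location by eigenvalue bisection, limit-cycle envelope
    scans, and a packaged model zoo centred on the NF-kB/IkBa/A20 feedback
    oscillator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
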