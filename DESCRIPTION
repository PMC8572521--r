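Package: phagestrat
Title: Bacteria-Phage-Nutrient Chemostat Dynamics Under Phage Infection Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a two-species bacterial community competing for a single
    limiting nutrient in a chemostat, with bacteriophage infection following one
    of three strategies: purely lytic, Piggyback-the-Winner (lysogeny at high
    host density) and Piggyback-the-Loser (lysogeny at low host density).
    The model couples Type-2 (Monod) nutrient uptake, density-dependent phage
    induction with a lysogenic/lytic growth switch, nutrient recycling via the
    viral shunt, and optional sinusoidal forcing of the chemostat turnover rate.
    Provides a compiled ODE right-hand side integrated with adaptive
    Runge-Kutta 5(4) stepping, plus an analysis layer: post-transient extrema
    detection, bifurcation scans over nutrient supply, persistence-state
    classification, two-dimensional fluctuation sweeps, and bisection estimates
    of extinction thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    utils,
    stats,
    tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
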