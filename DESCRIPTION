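Package: segwave
Title: Two-Module Models of Segmentation-Clock Arrest: SNIC Versus Hopf Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of developmental patterning models in
    which a line of cells transits from an oscillatory (clock) regime to a
    multistable (fate) regime under a regressing morphogen front. Implements
    a 3-gene transcriptional-module family (repressilator dynamic module,
    mutually repressing static module) and a planar geometric (gene-free)
    family, deterministic and stochastic (Euler-Maruyama with copy-number
    noise and diffusion) embryo simulations, numerical bifurcation diagrams
    with classification of the clock-arrest transition (SNIC, supercritical
    or subcritical Hopf, pitchfork), a phase-to-fate mutual-information
    metric of patterning precision, wave-shape metrics (sawtooth asymmetry,
    local wavelength and its analytic prediction), and a coupled
    phase-oscillator reference lattice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
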