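Package: navmarkov
Title: Markov-Chain Gating Models of the Cardiac Sodium Channel Nav1.5
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative Markov-chain gating schemes for voltage-gated ion
    channels, built around two-step-inactivation models of the cardiac sodium
    channel Nav1.5 (an 8-state fast-inactivation model and a 12-state model
    adding a slow-inactivated tier). Provides voltage-dependent rate laws with
    microscopic-reversibility-derived balancing rates, generator (Q) matrix
    assembly, spectral and Runge-Kutta propagation of state occupancies under
    piecewise-constant voltage-clamp protocols, the standard electrophysiology
    curve analyses (Boltzmann activation/availability, mono- and bi-exponential
    recovery and slow-inactivation development fits), a particle-swarm global
    optimizer with golden-section refinement for estimating rate constants from
    macroscopic currents, and a synthetic noisy-trace generator for closed-loop
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
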