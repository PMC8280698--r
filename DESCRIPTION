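Package: surfhop
Title: Decoherence-Corrected Trajectory Surface Hopping on Model Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fewest-switches trajectory surface hopping on analytic
    avoided-crossing model Hamiltonians, with three decoherence corrections
    operating behind a common plugin contract: the exact-factorization
    auxiliary-trajectory scheme (SHXF), energy-based exponential damping
    (SHEDC), and augmented fewest-switches stochastic collapse (A-FSSH).
    Includes Wigner sampling of harmonic ground-state initial conditions,
    isotropic and coupling-vector velocity rescaling with frustrated-hop
    policies, ensemble diagnostics (internal consistency, decoherence
    indicator, convergence harness), and a numerically exact split-operator
    wavepacket reference for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
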