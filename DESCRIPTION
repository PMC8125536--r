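Package: s2epr
Title: Spin-Hamiltonian Simulation and Decomposition of S2-State EPR
    Signals of the Photosystem II Manganese Cluster
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the continuous-wave electron paramagnetic resonance
    (CW-EPR) analysis of the S2 state of the photosystem II Mn4CaO5 cluster:
    construction and exact diagonalization of electron-spin and
    electron-nuclear spin Hamiltonians (Zeeman, zero-field splitting, cubic
    fine structure, 55Mn hyperfine), eigenfield resonance search and
    deterministic powder averaging to first-derivative field-swept spectra,
    closed-form and numerical Kramers-doublet effective g-values, a
    first-order model of the S2 multiline signal, illumination-difference and
    scaled-subtraction spectral decomposition with conversion-fraction
    estimation, bounded least-squares fitting of zero-field-splitting
    parameters with candidate spin-state comparison, and a seeded synthetic
    experiment generator emulating annealed and illuminated spectrum sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
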