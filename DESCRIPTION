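Package: siegertq
Title: Variational Quantum Identification of Molecular Resonances with
    Complex Absorbing Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies bound states and Siegert pseudostates (resonances)
    of a one-dimensional predissociation model by imposing purely outgoing
    boundary conditions with a complex absorbing potential (CAP) and
    chaining two simulated hybrid quantum-classical stages: variational
    quantum deflation of the Hermitian Hamiltonian followed by minimization
    of the pseudovariance of the non-Hermitian CAP Hamiltonian. Includes a
    Pauli-word operator algebra, exact/shot-sampled/noisy circuit
    simulators with thermal-relaxation and depolarizing channels, readout
    and zero-noise-extrapolation error mitigation, an arborescence task
    scheduler for batched asynchronous execution, and a classical
    exact-diagonalization reference with comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minqa,
    nloptr,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
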