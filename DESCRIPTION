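Package: qusrs
Title: Quantum Ultrafast Stimulated Raman Spectroscopy with Entangled Photons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coincidence-counted stimulated Raman spectroscopy of
    Frenkel-exciton aggregates driven by time-frequency entangled photon
    pairs. Builds the exciton Hamiltonian of a molecular aggregate,
    diagonalizes it, constructs thermal jump-operator dissipators and the
    Liouvillian, and propagates the reduced density matrix. Joint spectral
    amplitudes for entangled, uncorrelated and classical light are combined
    with six-point field correlators (including a brute-force Fock-space
    oracle verifying the Hong-Ou-Mandel cancellation of the dissipative
    pathway) to produce two-dimensional Raman-shift by arrival-time spectra,
    Hong-Ou-Mandel delay scans and resonance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse,
    dplyr
Config/testthat/edition: 3
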