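Package: rpdrive
Title: Driven Radical-Pair Spin Dynamics and Magnetic Compass Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the coherent spin dynamics of a recombining radical
    pair whose inter-radical distance is modulated in time, as in the
    cryptochrome-based model of avian magnetoreception. Builds spin
    Hamiltonians with Zeeman, hyperfine, exchange and electron-electron
    dipolar terms, applies Haberkorn singlet-selective recombination as a
    non-Hermitian effective Hamiltonian, and computes singlet recombination
    yields by Floquet stroboscopic propagation, direct stepwise integration,
    or stochastic trajectory ensembles over Brownian inter-radical motion.
    Provides directional magnetic-field-effect measures (relative anisotropy
    over axial orientations or an icosphere orientation grid), the relative
    entropy of coherence in the singlet-triplet basis, preset model systems
    (one-nitrogen, two-level, four-spin flavin-tryptophan), bounded optimal
    control of the driving waveform, and tidy parameter sweeps with ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
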