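Package: dynscat
Title: Dynamic X-Ray Scattering Simulation for XFEL Imaging of Organic Nanoclusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atomistic simulation of ultrafast coherent diffractive imaging of
    organic (sucrose) nanoclusters in intense X-ray free-electron-laser pulses.
    Provides a self-contained Hartree-Fock-Slater atomic-structure engine
    (orbital energies, photoionization and resonant cross sections, complex
    anomalous form factors via the optical theorem and Kramers-Kronig
    transform), Monte-Carlo rate-equation ionization dynamics coupled to
    classical nanoplasma molecular dynamics, time- and bandwidth-resolved
    coherent scattering cross sections, the homogeneous-sphere image model
    with diameter and fluence fitting for single-shot diffraction images, and
    the dynamic scattering efficiency (DSE) used to compare damaged and
    undamaged scattering response near the oxygen K-edge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    deSolve,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
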