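Package: thzenac
Title: Terahertz Spectral Analysis of Ion-Channel Inhibition from Dipole
    Dynamics and Cell-Suspension Spectra
Version: 0.1.0
Authors@R:
    person("THz", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse terahertz (THz) absorption of protein systems
    from both experiment and simulation. Implements solvent-baseline
    subtraction for cell suspensions via a displaced-volume model, baseline
    translation, point normalization, linear slope fitting and slope
    comparison of THz spectra; computation of IR/THz spectral densities from
    molecular-dipole time series via the autocorrelation/Wiener-Khinchin
    route over running trajectory windows; spectral convergence assessment
    with band-constrained exact dynamic time warping and the FastDTW
    approximation; trajectory geometry and energetics (Kabsch superposition,
    RMSD/RMSF, radial pair distribution functions, pairwise Coulomb and
    Lennard-Jones energies); and decomposition of ligand RMSD time series
    into quasi-stable states by multi-Gaussian peak fitting of the RMSD
    histogram. A synthetic-data module generates every input the pipeline
    consumes so all stages are testable without molecular-dynamics runs or
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
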