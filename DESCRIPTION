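Package: mbdtools
Title: Many-Body Dispersion Energies and Collective Charge-Fluctuation
    Analysis for Molecular Complexes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the many-body dispersion (MBD) model of van der
    Waals interactions, in which the valence response of each atom is
    represented by a charged quantum harmonic oscillator (Drude
    pseudoelectron).  From atomic coordinates and per-atom Hirshfeld
    volume ratios the package scales free-atom reference polarizabilities,
    screens them self-consistently through the short-range dipole
    potential (Dyson equation), assembles and diagonalizes the coupled
    oscillator Hamiltonian, and evaluates dispersion energies via the
    plasmon-pole formula and the equivalent random phase approximation
    log-determinant.  Downstream analysis tools compute interaction
    energies between molecular fragments, the pairwise Tkatchenko-Scheffler
    baseline, many-body energy decompositions, charge-density polarization
    from the correlated oscillator wavefunctions (Gaussian cube output),
    fluctuation-mode spectra, fragment-mode projections and a collectivity
    (inverse participation) measure of individual fluctuation modes.
    Includes a seeded synthetic-geometry generator and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
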