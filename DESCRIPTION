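Package: microhydrate
Title: Micro-Hydration Thermochemistry of Imidazole-Water Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explicit-solvation (cluster-continuum) analysis of
    imidazole-water clusters IMZ(H2O)n: multi-record XYZ input/output with
    fragment perception and imidazole ring-role labelling, rigid-rotor
    harmonic-oscillator (RRHO) ideal-gas thermochemistry, Boltzmann conformer
    ensembles and temperature-dependent populations, binding and incremental
    clustering energies, two-point complete-basis-set (CBS) extrapolation of
    SCF and correlation energies, deviation statistics (MAD/MAX/STD) for DFT
    functional benchmarking against a coupled-cluster reference, geometric
    hydrogen-bond detection and donor/acceptor censuses at the ring nitrogens,
    and cluster-continuum hydration enthalpy and free energy with
    convergence-in-n and temperature-dependence analysis. A rigid-body
    Lennard-Jones plus Coulomb sampler with mock electronic energies and
    harmonic frequencies generates complete synthetic study bundles so the
    whole pipeline runs without external quantum-chemistry software.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
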