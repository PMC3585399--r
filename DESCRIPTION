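Package: rlfep
Title: Entropic Ion Selectivity from Reduced Ligand Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale molecular-mechanics and alchemical free-energy toolkit for
    studying how restricting the thermal fluctuations of ion-coordinating ligands
    generates selectivity between Li+, Na+ and K+. Builds abstract n-ligand
    coordination cages from small dipolar ligands and simplified models of the
    LeuT and Glt_Ph sodium binding sites, samples them with Langevin dynamics,
    runs dual-topology restraint morphs and single-topology ion morphs through
    free energy perturbation (exponential averaging and Bennett acceptance
    ratio), and assembles the results into exchange free energies and their
    reduced-ligand-fluctuation component, including enthalpy and entropy
    decomposition, radial distribution functions, RMS fluctuations and
    occupancy-grid sampled volumes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
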