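Package: dendripH
Title: pH-Dependent Structural and Energetic Analysis of Peptide
    Dendrimer-siRNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the pH-dependent structure and energetics
    of cationic peptide dendrimers bound to short interfering RNA (siRNA)
    duplexes. Provides a coupled-site Monte Carlo titration model with an
    exact-enumeration oracle, Hill-equation pKa fitting of group titration
    curves (including phosphate- and groove-conditional apparent pKa
    values), geometric binding-mode statistics (position along the duplex,
    helix bending, major/minor groove mapping, amine-phosphate contacts),
    Shrake-Rupley solvent-accessible surface areas and phosphate
    electrostatic shielding, conditional free-energy landscapes from 2D
    kernel density estimates, protonation-weighted MM/PBSA binding free
    energy decomposition with a finite-difference Poisson-Boltzmann
    solver, and Wyman-Tanford proton-linkage free energy differences.
    A synthetic-ensemble generator builds bead-model dendrimer-duplex
    complexes with the statistical structure the analyses assume, so the
    whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    minpack.lm,
    bio3d,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
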