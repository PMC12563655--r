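Package: ionlattice
Title: Field-Gated Anion Transport in Nanoparticle Superlattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Brownian-dynamics generation and analysis of multivalent
    phosphate-anion transport in FCC nanoparticle superlattices under uniform
    electric fields. Provides a coarse-grained overdamped-Langevin simulator
    of rigid linear and cyclic anions in a fixed charged-nanoparticle lattice,
    compartment classification of anion centers (tetrahedral cavities,
    octahedral cavities, interparticle interface), residence-time survival
    analysis with double-exponential fitting and amplitude-weighted mean
    lifetimes, row-stochastic compartment transition matrices, ionic current
    and resistivity from drift velocities, and max-normalized planar density
    maps. Trajectories are exchanged as extended-XYZ (with GRO import).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
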