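Package: ecmigrate
Title: Individual-Based Simulation of Filopodia-Driven Cell Invasion into 3D
    Extracellular-Matrix Fiber Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A force-based, individual-based simulator of endothelial cell
    invasion into three-dimensional cross-linked collagen fiber networks.
    Couples semiflexible fiber-network mechanics (stretching and bending
    energies with virtual-work nodal forces), stochastic focal-complex
    formation at filopodial tips (Monte-Carlo receptor-ligand binding and
    Bell slip-bond rupture), acto-myosin contraction with a muscle-type
    force-velocity law, a seven-state filopodium phase machine, simplified
    triple-membrane cell-body mechanics, and finite-volume
    reaction-diffusion of seven biochemical species driving proteolytic
    matrix degradation.  Includes a procedural fiber-network generator with
    controlled pore size, an in-silico uniaxial stretch-test protocol with
    bulk-modulus fitting, and full invasion simulations reporting
    filopodial tip and root penetration speeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
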