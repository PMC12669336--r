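Package: ngvu
Title: Multiscale Simulation of the Neuro-Glial-Vascular Unit
Version: 0.1.0
Authors@R: person("NGVU", "Maintainers", email = "ngvu@example.org",
    role = c("aut", "cre"))
Description: Simulates blood supply and cellular signalling in a
    neuro-glial-vascular unit. Couples pulsatile one-dimensional arterial
    haemodynamics with Windkessel outlets to a capillary bed through a
    Murray-law surrogate tree, solves stationary 3D-1D coupled perfusion and
    solute transport on a capillary graph embedded in tissue, and drives
    vessel radius dynamically from a quadripartite synapse model (Hodgkin-
    Huxley spiking, bouton calcium, stochastic vesicle release, astrocyte
    G-ChI dynamics) through a neurovascular coupling chain (KIR input,
    SMC/EC exchange, Hai-Murphy cross-bridges, Kelvin-Voigt wall mechanics,
    nitric-oxide/cGMP pathway). Includes one-at-a-time, Latin-hypercube/PRCC
    and local-elasticity sensitivity analysis of the wall mechanics.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
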