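Package: chloridyn
Title: Chloride and Bicarbonate Dynamics of GABAergic Signalling in Immature Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying activity-dependent intracellular chloride
    plasticity in immature hippocampal neurons. Implements the
    Goldman-Hodgkin-Katz based determination of intracellular chloride from
    the GABA-A reversal potential (with bicarbonate permeability), analysis
    of current- and voltage-clamp traces (online detection of giant
    depolarizing potentials, voltage-ramp reversal-potential extraction,
    post-synaptic current detection and charge integration), a
    multicompartment passive cable simulator with concentric-shell
    intracellular Cl-/HCO3- diffusion and transport, the in-silico
    access-resistance, space-clamp and network-event protocols built on it,
    and seeded generators of surrogate morphologies and synthetic
    recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
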