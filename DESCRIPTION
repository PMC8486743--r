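Package: crnsim
Title: Mass-Action Reaction-Network Simulation of Mutations and Targeted Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates signaling chemical reaction networks under mass-action
    kinetics and quantifies the network-wide effect of loss-of-function and
    gain-of-function mutations and of competitive-inhibitor drugs.  Networks
    are read from SBML or from a plain reaction-table dialect; moiety
    conservation laws are computed from the exact left null space of the
    stoichiometric matrix; equilibria are obtained by stiff ODE integration
    within a stoichiometric compatibility class; mutations are modelled as
    projections of the conserved totals (loss of function) or removal of
    deactivation reactions (gain of function), drugs as reversible binding of
    a competitive inhibitor, with per-species relative-difference profiles,
    flux decompositions and dose titration as read-outs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
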