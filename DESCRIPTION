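Package: spinesim
Title: Kinetic Simulation of Dopamine- and Calcium-Dependent Signaling in
    Striatal Spines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action simulation of the signaling cascade in
    dendritic spines of D1-receptor-expressing striatal medium spiny neurons.
    Provides a generic reaction-network core built from binding and enzymatic
    reactions (with conservation-law extraction and stiff ODE integration via
    'deSolve'), a concrete 72-reaction model of the dopamine-D1R-cAMP-PKA and
    calcium-calmodulin pathways converging on DARPP-32 and AMPA-receptor
    trafficking, alpha-function stimulus protocols, in-silico plasticity
    experiments (knockouts, pathway ablations, activity clamps, input-timing
    and basal-dopamine studies), and a Newton-based steady-state and
    bifurcation engine for the PKA-PP2A-Thr75 positive feedback loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
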