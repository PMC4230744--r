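Package: nigrosim
Title: Stochastic Neural Population Modelling of Nigro-Cortical Dopamine
    Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-brain neural population dynamics as a system of
    coupled stochastic differential equations in which a nigro-cortical
    dopamine pathway (substantia nigra pars compacta projecting to the
    laryngeal motor cortex) modulates regional excitability during a
    speech-production task. Provides a strong order-1.5 explicit
    Runge-Kutta integrator adapted to constant additive scalar noise, an
    Euler-Maruyama reference scheme, Michaelis-Menten dopamine release and
    re-uptake kinetics, Balloon-Windkessel conversion of firing rates to
    simulated BOLD signal, normalized-mutual-information functional
    connectivity, weighted graph metrics with null-model normalization, a
    max-statistic paired permutation test, and generators for synthetic
    structural connectomes and region manifests so the full rest-versus-task
    experiment runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
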