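Package: motifadapt
Title: Adaptive Biochemical Network Motifs under Dynamic and Spatial Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of adaptive biochemical network motifs
    (inflow-outflow circuits, incoherent feedforward loops, transcritical /
    autocatalytic circuits and hybrid combinations) driven by dynamic and
    spatial stimuli. Provides a closed registry of circuit models with
    configurable signal sites, parametric stimulus families (steps, ramps,
    sinusoids, static gradients, travelling and standing waves), stiff ODE
    integration and method-of-lines reaction-diffusion on a 1-D periodic
    domain, a response taxonomy (exact / partial / non-adaptive / unbounded),
    period-mean and spatial-mean diagnostics, closed-form analytic
    predictions for steady states and maintained means, and a reproducible
    experiment suite that assembles the qualitative circuit-by-stimulus
    combination matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
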