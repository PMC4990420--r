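Package: prebotsim
Title: Embryonic preBotzinger Pacemaker-Neuron Modelling and Burst Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Conductance-based single-cell model of an embryonic preBotzinger
    complex inspiratory pacemaker neuron, combining a persistent sodium
    current (I_NaP) burster with a calcium-activated nonspecific cation
    current (I_CAN) driven by two-pool (cytosol/endoplasmic reticulum) IP3
    receptor calcium dynamics.  The package integrates the model with a
    stiff adaptive solver, quantifies burst drive potentials (amplitude,
    duration, depolarization block), classifies discharge phenotypes
    (silent, tonic, oscillatory, plateau, mixed), maps discharge regimes
    over the gNaP x gCAN conductance plane, runs in-silico pharmacology
    (riluzole, flufenamic acid, 9-phenanthrol), scores rhythmicity and
    phase locking of calcium-imaging dF/F traces, and generates fully
    seeded synthetic voltage, dF/F and synaptic-current traces with ground
    truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
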