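Package: awapulse
Title: Negative-Feedback Model of GPCR-Driven Calcium Pulses in the AWA Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a parsimonious negative-feedback model of
    GPCR-to-calcium signaling in the C. elegans AWA chemosensory neuron,
    in which logarithmic receptor coding, a self-amplifying channel switch
    and integral feedback inhibition produce exact adaptation to odor
    steps and pulsatile coding of smooth gradients. Provides stimulus
    protocol constructors (steps, two-step habituation schedules,
    repetitive trains, sigmoidal and linear gradients), stiff ODE
    simulation with a compiled right-hand side, calcium pulse detection
    for both experimental-style and simulated traces, habituation and
    interpulse-interval analyses, exponential decay fitting, parameter
    and stimulus-amplitude robustness scans, and a synthetic GCaMP
    fold-change trace generator for testing analysis pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
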