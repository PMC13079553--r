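Package: dendrocable
Title: Semi-Analytical Cable Theory and Model Reduction for Branched Dendrites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for morphologically detailed neuron models built on
    one-dimensional cable theory. Reads SWC morphologies into trees of
    cylindrical sections with a continuous coordinate system, attaches
    Hodgkin-Huxley style ion channels defined symbolically, and linearizes
    them into quasi-active membranes. Computes input and transfer impedances
    of the linearized model in the frequency domain with Koch's recursive
    algorithm, inverts them to time-domain response kernels, and extracts
    separation-of-variables eigenmode expansions (decay time constants and
    capacitance-normalized spatial modes) for passive trees. Reduced
    compartmental models are derived by least-squares fitting of resistance
    matrices over multiple expansion points, including capacitance,
    ion-concentration pool and leak-reversal fits, and are validated against
    a built-in second-order finite-difference simulator with current and
    synaptic stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
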