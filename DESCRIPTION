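Package: adaptmmn
Title: Adaptation-Model Simulations of Auditory Mismatch Negativity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Neural mass model of primate auditory cortex built from lumped
    excitatory/inhibitory cortical columns arranged into core, belt and
    parabelt fields plus a thalamic (MGN) input stage, coupled by topographic
    feedforward, feedback and lateral connections and modulated by short-term
    synaptic depression. Generates seeded stimulus protocols for classic
    mismatch-negativity paradigms (stimulus omission, unexpected repetition,
    local-global deviance, oddball with multi-standard control, anisochronous
    oddball), integrates the network dynamics, computes an MEG proxy signal,
    and derives event-related fields with peak and difference-wave metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
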