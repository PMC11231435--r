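Package: sinet
Title: Swim Interneuron Dynamics and Two-Cell Rhythm-Generating Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Conductance-based modelling toolkit for sea-slug swim central
    pattern generator building blocks. Implements the swim-interneuron model
    (an adapted Plant R15 burster with slow-subsystem shift parameters and an
    h-current), five synapse kinetics models (fast threshold modulation,
    alpha, higher-order cascade, dynamic, and logistic), slow-fast dissection
    of the cell's (calcium, x) phase plane (critical manifolds, averaged
    nullclines, SNIC curve), trace-based activity classification and
    two-parameter regime scans, and a two-cell network simulator for
    half-center oscillator and excitatory/inhibitory modules with burst
    metrics, phase lags, and bistability probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
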