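Package: angioctrl
Title: Closed-Loop Backstepping Control of Tumour Growth Under
    Anti-Angiogenic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates automatic dosing of an angiogenic inhibitor for a
    two-state tumour-growth model (tumour volume and inhibitor serum level)
    under a positive-input backstepping control law that feeds back only the
    measured tumour volume. Provides the control law and its gain condition,
    a stiff closed-loop simulator with optional sinusoidal measurement noise,
    zero-order-hold sampled feedback and plant-parameter perturbation, and a
    numerical verification suite for the exponential-stability (Lyapunov)
    envelope and the bounded-input bounded-output robustness envelope, plus a
    registry of reference scenarios and a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
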