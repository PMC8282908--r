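Package: cobci
Title: Collaborative Motor-Imagery Brain-Computer Interface Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding framework for collaborative motor-imagery
    brain-computer interfaces (cBCI). Generates multi-subject epoched EEG with
    planted event-related desynchronization (ERD), reproduces a six-instruction
    motor-imagery pipeline (common average reference, 8-28 Hz band-pass,
    one-vs-rest common spatial patterns, linear support vector machines with
    leave-one-out accuracy weights), builds division-of-work task-allocation
    schemes for five-user groups, and evaluates feature-level and
    decision-level multi-user fusion in pseudo-online classification,
    including the accuracy-versus-tasks-per-user curve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
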