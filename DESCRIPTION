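Package: surpsal
Title: Language-Model Surprisal and Saliency Encoding of Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Derives word-level surprisal and context-word saliency
    (gradient-times-input) from an autoregressive language model over
    sliding text windows, converts them into hemodynamic-response-convolved
    fMRI regressors, and fits two-level ROI-based encoding GLMs contrasting
    forward versus backward narrative listening. Includes an analytic toy
    language model with a finite-difference gradient oracle and a synthetic
    data generator (timed transcripts, audio-envelope nuisance series,
    multi-subject two-condition ROI BOLD with planted effects) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
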