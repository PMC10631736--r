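Package: patterncell
Title: Pattern and Component Cell Analysis for Visual Motion Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether direction-tuned visual neurons are
    true nonlinear motion integrators ("pattern cells") or linear edge
    detectors ("component cells"). Implements drifting grating, plaid and
    correlated-noise stimulus synthesis; synthetic linear-nonlinear, energy
    and pooled-pattern model neurons with Poisson spiking; direction tuning
    metrics (DSI, modulation index, cross-orientation suppression index);
    the Zp/Zc partial-correlation classification; spike-triggered-average
    receptive-field estimation with decorrelation, permutation z-scoring,
    Gabor fitting and lobe counting; LN-model tuning prediction and
    reclassification; and regressor-bank linear models of tuning curves with
    cross-validated model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    EBImage,
    minpack.lm,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
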