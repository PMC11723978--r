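Package: lickchoice
Title: Development of Lick-Locked Choice Activity in Auditory Cortex Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how decision-related (lick-locked,
    sound-gated) population activity develops with task experience in auditory
    cortex two-photon recordings. Provides a session data model for deconvolved
    event-rate traces with lick and stimulus event trains, trial-outcome parsing
    and signal-detection performance for a delayed tone-detection task,
    lick-burst microstructure, Wilcoxon-based functional cell classification
    (enhanced / suppressed / non-modulated, sound-responsive), windowed
    trial-to-trial noise correlations, CCA alignment of latent population
    dynamics across experience stages with resampled bounds, and population
    decoding of pre- versus post-sound licks (PCA, minority oversampling,
    RBF-SVM, cross-validation). A synthetic-session generator with planted
    ground truth emulates the task and neural statistics so every stage is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
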