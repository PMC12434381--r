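Package: gspred
Title: Graph-Signal-Processing Features for Behavior Prediction from
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares nine resting-state fMRI feature subtypes (functional
    connectivity, regional signal statistics, and graph-signal-processing
    features defined on connectome harmonics) for predicting behavioral
    targets. Implements parcel-level denoising, consensus structural
    connectome construction with its normalized-Laplacian harmonic basis,
    the graph Fourier transform and graph filtering, coupled/decoupled
    functional connectivity and the structural decoupling index, a
    family-aware nested cross-validation prediction framework with a
    permutation-based significance test, and sample-size by scan-time
    scaling experiments. Ships a synthetic cohort generator with known
    ground truth so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    signal,
    data.table,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
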