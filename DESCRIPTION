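Package: driftframe
Title: Longitudinal Stability Analysis of Calcium-Imaging Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify representational drift in multi-day one-photon
    calcium imaging of neuronal populations during a two-choice maze task.
    Provides a synthetic-data generator with known ground truth (place-field-like
    trajectory-specific tuning, configurable cross-day drift, activity dropout),
    trace preprocessing (baseline percentile filtering, iterative z-scoring,
    significant-transient and rising-phase detection), trajectory linearization
    and spatial tuning functions with spatial information and side index,
    cross-day tuning correlations with shuffle nulls and a drift surrogate,
    population-vector edge-angle geometry, cross-day position and trial-outcome
    decoders, generalized-linear-model variance partitioning with permutation
    significance, and probabilistic longitudinal cell registration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
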