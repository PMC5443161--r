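Package: rpbci
Title: Ternary Readiness-Potential Classification for Self-Paced
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-trial classification of pre-movement EEG (readiness
    potentials) into idle, left-hand and right-hand movement states. Implements
    a pipeline of spatio-temporal filtering (zero-phase Butterworth band
    filtering, EOG artifact regression, a regularized Fisher-criterion
    beamformer and non-overlapping window averaging) with per-subject
    hyperparameter optimization, five probabilistic classification algorithms
    behind one contract, ternary classification by direct multiclass modelling
    or binary decomposition (one-against-one with pairwise coupling,
    one-against-all, directed binary tree, decision directed acyclic graph),
    an ordered diversified classifier system with reliability-weighted
    posterior fusion, Cohen's kappa evaluation under a trial-level 10-chunk
    cross-validation protocol, and a synthetic readiness-potential EEG
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    nnet,
    signal,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
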