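Package: erpca
Title: Condition-Wise Temporal PCA of Go/NoGo Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for decomposing auditory Go/NoGo
    event-related potentials (ERPs) into temporal principal components,
    separately per drug and stimulus condition. Covers simulation of
    crossover Go/NoGo EEG sessions with planted ERP components, ocular
    artifact regression, zero-phase low-pass filtering, epoching, artifact
    and behavioral trial rejection, covariance-based temporal PCA with
    Kaiser-normalized Varimax rotation, component selection and labelling,
    cross-condition component matching by Tucker congruence, and planned
    repeated-measures topographic contrasts with directional p-values and
    partial eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
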