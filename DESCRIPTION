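Package: latreact
Title: Unsupervised Detection of Lateralised Behavioural Reactions to
    Sound in Infants and Toddlers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the direction of infant and toddler
    behavioural reactions to lateralised sound presentations from
    non-identifiable, video-derived facial features (head pose, eye gaze
    and facial action-unit activations in the OpenFace column dialect).
    Provides a seeded synthetic-session generator emulating a
    sound-booth test protocol, single-frame feature extraction at a
    fixed post-onset delay, four two-dimensional feature projections
    (head rotation, left-eye gaze, averaged gaze angles, first two
    principal components), a from-scratch three-component bivariate
    Gaussian-mixture EM with exhaustive initialisation, short-EM and a
    sign-opposition restart criterion, cluster-to-direction labelling,
    and validation statistics (contingency tables, correct-decision
    rates, exact one-sided binomial tests and head/gaze decision
    combination).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
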