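Package: aesthsim
Title: Simulation and Analysis of Aesthetic Experience Across Perception
    and Mental Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study whether aesthetic experiences evoked by
    visual perception and by mental imagery are behaviorally equivalent
    and how they are encoded in multivoxel activity patterns. Provides a
    synthetic-data generator that plants known ordinal rating effects and
    known representational geometries; a behavioral pipeline with a
    cross-modality dissimilarity score, hierarchical Bayesian cumulative
    probit and Student-t regressions fitted by an adaptive
    Metropolis-within-Gibbs sampler, and region-of-practical-equivalence
    (ROPE) Bayes factors; construction of neural representational
    dissimilarity matrices (RDMs) and a theory-derived candidate model
    family over modality, experience and stimulus type; and
    representational similarity inference with whitened cosine
    similarity, noise ceilings, subject-level bootstrap and multiple
    comparison corrected model tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
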