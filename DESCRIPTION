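Package: proprioadapt
Title: Robotic Assessment of Proprioception and Visuomotor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for robotic (Kinarm-style) assessments of
    upper-limb proprioception and visuomotor adaptation after stroke.
    Computes arm position-matching metrics (absolute error, variability,
    workspace area, spatial shift) and arm movement-matching metrics
    (response latency, peak-speed ratio, initial-direction error,
    path-length ratio) from planar hand trajectories, builds normative
    task scores through a z/zeta, root-sum-square and Box-Cox scoring
    chain with a 1.96 impairment cutoff, summarises visuomotor-rotation
    sessions (initial/final adaptation, trials to adapt) against
    empirical control ranges, and relates proprioceptive to adaptation
    impairments with bootstrap tests, Spearman correlations, Fisher
    exact independence tests and Bonferroni-Holm correction. Includes a
    synthetic-cohort generator with a trial-by-trial state-space learner
    so the full pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
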