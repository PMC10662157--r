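Package: swatrsa
Title: Behavioral Representational Similarity Analysis for Word-Arrangement Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired-associate learning experiments that
    measure semantic structure with a similarity-based word arrangement task
    (SWAT). Builds per-participant representational similarity matrices from
    2D canvas placements (evidence-weighted scaled-to-match combination of
    partial trial distance matrices, k-nearest-neighbor imputation of
    structurally unmeasured pairs), scores typed cued-recall responses with
    spell tolerance, and computes representational-change statistics:
    pairwise similarity change, 20-nearest-neighbor word-level change,
    cue/target asymmetry, semantic-lure interference by similarity bin, and
    normative-alignment change. Includes the inferential layer (repeated
    measures ANOVA with generalized eta-squared, Holm-adjusted t tests,
    mixed-effects model contracts) and a synthetic-data generator with an
    explicit model of learning-induced semantic distortion for ground-truth
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
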