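Package: artgrowth
Title: Pragmatic Trial Emulation of Assisted Reproduction Effects on Child Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for emulating a pragmatic trial of assisted
    reproductive technology (ART) conception versus spontaneous conception in
    a birth cohort, and for estimating ART effects on child anthropometry.
    Provides a synthetic cohort generator with known ground-truth causal
    structure; rule-based comparison-arm construction from subfertility and
    paternal risk indications; clinical derivation formulas (Shepard
    estimated fetal weight, HOMA indices, LMS z-scores, blood-pressure
    protocol averaging); multiple imputation by chained equations with
    Rubin's-rules pooling; covariate-adjusted and inverse-probability-weighted
    effect estimation; a cross-validated stacking ensemble and collaborative
    targeted maximum likelihood estimation of the average treatment effect;
    candidate-CpG methylation association scans with Bonferroni control and a
    two-round clump-and-threshold polygenic score; and parametric
    g-computation mediation (total, natural direct and indirect effects) with
    bootstrap inference and a negative-control maternal-methylation ordering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    glmnet,
    xgboost,
    pracma,
    sandwich,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
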