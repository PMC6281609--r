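Package: qtgtest
Title: Quantitative Complementation and Causal Inference Testing for
    Quantitative Trait Gene Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for validating a candidate quantitative
    trait gene (QTG) in mouse crosses: simulation of four-way cross and F2
    intercross cohorts with litter structure and a configurable
    genotype-expression-trait mediation model; linear mixed-model trait
    adjustment (fixed-effect selection at a nominal level, litter random
    intercept, optional body-weight covariate); the quantitative
    complementation test (two-way allele-interaction ANOVA and the
    complement/failure-to-complement call); one-way ANOVA, Tukey HSD with
    compact letter display, and MANOVA over trait groups; relative qPCR
    expression by the 2^-ddCt method; and the four-component causal
    inference test (CIT) classifying genotype-expression-trait triples as
    causal, marginally causal, or not causal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    emmeans,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
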