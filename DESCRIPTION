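Package: icdepth
Title: Vector-Sum and Maximum-Likelihood Models of 3D Depth-Cue Integration
Version: 0.1.0
Authors@R:
    person("ICDepth", "Developers", email = "icdepth@example.org",
           role = c("aut", "cre"))
Description: Observer models and analysis tools for 3D depth-cue combination
    experiments. Implements the intrinsic-constraint (vector-sum) combination
    rule and its linear maximum-likelihood (MLE) rival as generative observer
    models, a transformed up-down staircase engine for two-interval
    forced-choice (2IFC) depth discrimination, cumulative-Gaussian psychometric
    fitting (PSE/JND), Weber-law task-noise modelling of discrimination
    thresholds, cue-strength estimation with parameter-free combined-cue
    predictions, and a simplified inferential layer (repeated-measures ANOVA,
    Bonferroni paired t tests, random-intercept mixed models, BIC-approximate
    Bayes factors). Synthetic-observer generators emulate probe-adjustment and
    staircase experiments so that every analysis stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
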