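Package: dermselect
Title: Quantum-Behaved Particle Swarm Feature Selection for Skin-Lesion
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Wrapper feature selection for multi-class skin-lesion
    classification built on a quantum-behaved particle swarm optimizer
    (QBPSO). Provides the optimizer core with an annealed
    contraction-expansion coefficient, a binary feature-selection mode scored
    by label-smoothed cross-entropy with a sparsity penalty, the
    mobile-inverted-bottleneck (MBConv) computational blocks of a compact
    EfficientNet-style feature extractor with squeeze-and-excitation and
    self-attention refinement, SMOTE class balancing with stratified
    splitting, a full confusion-matrix metric suite (per-class
    precision/recall/FNR/F1/specificity/FPR, Matthews correlation,
    bias-corrected kurtosis, ANOVA and t comparisons of Monte-Carlo runs),
    and an end-to-end pipeline exercisable entirely on synthetic
    lesion-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
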