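Package: mdassoc
Title: MiRNA-Disease Association Prediction via Similarity Kernel Fusion
    and Space Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a Boolean
    association matrix and multiple precomputed similarity kernels. Three
    kernels per entity type (for miRNAs: functional, sequence, and Hamming
    interaction-profile similarity; for diseases: semantic, functional, and
    Hamming) are fused by sparse-kernel cross-diffusion with mutual-neighbor
    noise weighting. The fused similarities reweight the bipartite
    association network, and candidate pairs are ranked by combined miRNA-
    and disease-space projection scores. Includes global leave-one-out
    cross-validation with full per-fold recomputation, new-miRNA and
    isolated-disease masking protocols, parameter sweeps, a block-structured
    synthetic data generator, broom-style tidiers, and ggplot2 ROC plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
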