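Package: bwasrep
Title: Replicability Analysis for Multivariate Brain-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the replicability of multivariate brain-wide
    association studies (BWAS). Implements paired discovery/replication
    bootstrap experiments with cross-validated versus in-sample effect-size
    estimation, permutation null distributions, power and replication
    probability (P_rep) metrics, publication-bias (winner's curse) conditional
    inflation, and closed-form Fisher-z power and sample-size calculations for
    prediction-outcome correlations. Ships a synthetic-data generator that
    emulates connectome-style correlated features with a controllable true
    multivariate effect size, plus the two standard prediction pipelines
    (PCA followed by linear support-vector regression, and ridge regression
    on partial-correlation features).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
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
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
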