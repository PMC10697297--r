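Package: labprogress
Title: Two-Stage Pretraining of Laboratory-Trajectory Forecasters for
    Clinical Event Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning disease-progress representations from
    irregular longitudinal laboratory time series. Monthly timelines are
    reconstructed by linear, shape-preserving cubic (PCHIP) or barycentric
    polynomial interpolation, framed into fixed-length sliding windows with
    per-month certainty masks, and used to train a small per-marker
    recurrent forecaster (a bidirectional LSTM with a condensing layer and
    a two-layer regressor) in two stages: supervised next-month prediction
    on interpolated frames, then autoregressive self-supervised refinement
    on non-interpolated windows targeting the last real observation. The
    frozen forecasters convert episodic single-visit records into
    progress representations for downstream binary event classification
    with gradient-boosted trees, support vector machines, logistic
    regression and k-nearest neighbours, including classifier-agreement
    analysis via Cohen's kappa. A seeded synthetic cohort generator
    emulating three-monthly visit schedules with dropout and jitter
    supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
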