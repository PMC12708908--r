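Package: dyadsync
Title: Physiological Synchrony and Affect Regression for Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the valence and arousal of dyadic
    conversation intervals from autonomic nervous system recordings.
    Includes a synthetic generator of coupled two-person recordings
    (ECG, electrodermal activity, respiration, skin temperature),
    R-peak / breath-peak / skin-conductance-response detection,
    twenty per-participant autonomic features, nine inter-partner
    synchrony measures (dynamic time warping and derivative and
    complexity-invariant variants, nonlinear interdependence,
    coherence, cross-correlation, cosine, Hausdorff and symmetric
    segment-path distances) on four signal modalities, MRMR and
    Laplacian-score feature selection, and dyad-specific and
    dyad-nonspecific crossvalidated regression (Levenberg-Marquardt
    multilayer perceptron, regularized linear regression, Gaussian
    support vector machine, median-based baseline) with mean-absolute
    and root-mean-square error evaluation and paired method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
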