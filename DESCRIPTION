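Package: wagdyn
Title: Kinematics, Laterality and Attractor-Like Dynamics of Dog Tail Wagging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-tracking analysis of dog tail-wagging behaviour from 3D
    keypoint trajectories (withers, back, croup, tail tip).  Provides
    preprocessing of pose-estimation output (likelihood filtering, Gaussian
    smoothing, body-frame alignment, stillness masking), extraction of the
    three wagging kinematic parameters (signed angle, amplitude, angular
    velocity) and wagging bouts, quantification of left-right wagging
    asymmetry per kinematic bin, per 20-s segment and per day, unsupervised
    bout clustering by dynamic time warping and affinity propagation with
    silhouette validation and per-session behavioural fingerprints, and a
    Lyapunov-stability analysis (Wolf largest-Lyapunov-exponent estimator on
    delay embeddings) that segments wagging into stable and transient modules
    with transition graphs and ethograms.  A synthetic trajectory generator
    with known ground truth (motifs, side labels, stillness) supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
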