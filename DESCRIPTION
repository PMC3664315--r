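Package: bbseg
Title: Bayesian Binning Segmentation of Movement Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of 3D end-effector trajectories into
    movement primitives by Bayesian binning: exact posterior inference over
    all partitions of a discretized time axis into contiguous segments, each
    described by a multivariate Gaussian observation model with a polynomial
    time-dependent mean and a conjugate extended Gauss-Wishart prior.
    Includes differential-invariant kinematics (speed, Euclidean curvature),
    generalized speed-curvature power-law regression with compliance scoring,
    a power-law ground-truth synthesizer based on spline time warping, and a
    hit-rate / false-positives-per-second evaluation protocol with a Poisson
    line of no discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
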