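Package: pathgaze
Title: Gaze and Path-Choice Analysis for Walking Obstacle Avoidance
Version: 0.1.0
Authors@R:
    person("pathgaze", "developers", email = "maintainer@pathgaze.org",
           role = c("aut", "cre"))
Description: Tools for analysing how walkers choose a path around an obstacle
    on the way to a reaching target, and the gaze behaviour that accompanies
    the decision. Builds walkway/obstacle layouts and derives the decision
    geometry (relative distance, deviation angles, avoidance margins and
    their ratio); simulates complete trial datasets (choices, trajectories,
    gaze streams, judgment-test ratings) with the statistical structure the
    analysis assumes; computes area-of-interest gaze dwell, allocation maps
    and the avoidance-margin gaze ratio; encodes duration-normalised
    100-symbol gaze scanpaths, scores their similarity by Needleman-Wunsch
    global alignment and summarises condition groups by dynamic-time-warping
    barycenter averaging; fits univariate and L1-sparse multivariate logistic
    choice models with surrogate bootstrap inference, effect partitioning,
    leave-one-out cross-validation and psychometric threshold estimation; and
    orchestrates the whole analysis as a reproducible, seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
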