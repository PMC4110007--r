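Package: submovekit
Title: Minimum-Jerk Submovement Decomposition and Closed-Loop Prediction of 3D Arm Reaches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing target-directed three-dimensional arm reaching
    movements as superpositions of overlapping minimum-jerk submovements.
    Provides preprocessing of fingertip kinematics (resampling, occlusion
    interpolation, zero-phase low-pass filtering), decomposition of measured
    velocity trajectories into minimum-jerk basis functions by regularised
    nonlinear least squares with knee-point model-order selection, causal
    kinematic feature extraction, small feed-forward neural networks that
    predict submovement initiation time, amplitude and duration, and a
    closed-loop simulator that chains the three predictors into a corrective
    reach-trajectory generator. Includes a synthetic reach generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
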