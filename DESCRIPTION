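Package: footbvr
Title: Synthetic Comparison of Biplanar Videoradiography and Optical
    Motion Capture for Multi-Segment Foot Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully synthetic, seeded pipeline for studying the agreement
    between biplanar videoradiography (BVR) and optical motion capture (OMC)
    measurements of foot and ankle kinematics. Generates voxel bone phantoms
    with Rizzoli-model skin-marker landmarks, ground-truth stance-phase bone
    pose trajectories, two calibrated x-ray views with digitally reconstructed
    radiograph (DRR) image stacks, and soft-tissue-artifact-corrupted marker
    trajectories. Provides markerless bone-pose tracking by normalized
    cross-correlation of DRRs with downhill-simplex optimization and
    quaternion-spline keyframe interpolation, bead-cube camera calibration by
    direct linear transformation, undistortion-grid fitting, drop-trial
    temporal synchronization, rigid-body co-registration by SVD Procrustes,
    virtual-marker synthesis, ankle Cardan angles and medial longitudinal arch
    angle computation, and waveform agreement statistics (linear fit method,
    RMSE, per-marker RMS trajectory differences, nonparametric group tests).
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
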