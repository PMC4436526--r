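Package: dyadkin
Title: Two-Person Imitation Kinematics: Dyad Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for imitation accuracy in actor/imitator dyads
    recorded with a multi-tracker 6-DOF motion capture system. Implements
    kinematic preprocessing (acceleration-based despiking, zero-phase
    Butterworth low-pass filtering, frame rotation, video-latency correction,
    movement-based trial segmentation), derivation of arm joint angles, grip
    aperture and grip position, lag-scanned cross-correlation coupling
    statistics with Fisher r-to-Z aggregation, and within-subject 2x2
    factorial tests (univariate and Hotelling multivariate). A synthetic dyad
    generator emulating a pegboard ball-moving task provides ground-truth
    recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
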