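Package: lamigrind
Title: Cutter-Tip State Estimation for Laminar Bone Grinding from CT-Derived Force Templates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing the tip of a ball-end milling cutter during
    layer-by-layer laminar bone grinding. A mechanistic ball-end milling force
    model, weighted by normalized CT grayscale as a bone-strength proxy, turns a
    planned milling path over a CT volume into a bank of per-grid four-channel
    force/torque template sequences. Intra-operative force signals are segmented
    by a tumbling window and matched to the bank by dynamic time warping (or a
    Pearson-correlation baseline) to estimate the instantaneous tip position;
    RANSAC line fitting and a rigid-offset geometric constraint then estimate
    the workspace deviation and milling depth. Includes synthetic stepped-gradient
    and lamina-like CT phantom generators, a voxel-carving engagement oracle, and
    a closed-loop simulation harness with pose deviation, feed-rate disturbance
    and sensor noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
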