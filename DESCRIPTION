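Package: coneFuse
Title: Cone-Marker-Based Fusion of MicroCT Volumes and Histological Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Localizes 2D histological sections inside 3D microCT volumes using
    3D-printed truncated-cone fiducial markers. Implements slice-wise rule-based
    detection of conic cross-sections (adaptive thresholding, Canny edges,
    morphology, direct least-squares ellipse fitting), a pluggable promptable-mask
    segmentation backend, two-pass robust calibration of each cone's linear
    width-height taper, matching of section ellipses to cones, three-point
    affine plane embedding with trilinear oblique-slice extraction, rigid
    mean-squared-error registration, and a contrast-inversion-robust local
    normalized cross-correlation (LNCC) score with heatmaps and layer-sweep
    validation. A synthetic phantom generator with analytic ground truth
    replaces the physical printing, embedding and scanning chain so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
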