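Package: fluorosyn
Title: Synthetic Fluoroscopy Scenes and Dual-Mode Tracking of Miniature Medical Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates auto-labelled, domain-randomized synthetic X-ray scenes of
    miniature medical devices (MMDs): three-channel conditioning masks (tissue,
    metallic device, contrast-filled lumen), procedural greyscale backgrounds,
    periodic-spline shape synthesis for deformable liquid devices, and
    contrast-controlled alpha-blend compositing that emits pixel-accurate polygon
    instance labels without manual annotation. Includes patch-based tiling for
    small-object inference, a dual-mode (global-search / local-ROI) tracking loop
    with five-criterion detection gating and adaptive Kalman interpolation through
    occlusions, and evaluation metrics (AP, mAP50, mAP50:95 for boxes and masks,
    Michelson contrast, MAD-based noise estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
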