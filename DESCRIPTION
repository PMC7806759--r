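Package: ecgdelnet
Title: ECG Wave Delineation with 1D U-Nets Trained on Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Frames electrocardiogram (ECG) delineation -- locating the
    onset, peak and offset of the P, QRS and T waves -- as a one-dimensional
    semantic segmentation problem. Per-beat fiducial annotations are encoded
    as three-channel binary occupancy masks, a configurable 1D U-Net
    (vanilla, residual or depthwise-separable convolutional blocks, batch
    normalization, spatial dropout) is trained on them with a soft Jaccard
    loss, Adam optimization and ECG-tailored signal-to-noise-calibrated data
    augmentation, and predictions are decoded back to fiducials and scored
    with correspondence-matrix detection metrics, onset/offset error
    statistics and observer-bias estimators. Includes a synthetic multi-lead
    ECG generator with exactly known fiducials, a minimal WFDB-style signal
    and annotation reader/writer, subject-wise cross-validation and
    semi-supervised pre-training on degraded labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
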