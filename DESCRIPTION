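Package: hfsnet
Title: Hierarchical Fusion Segmentation Networks for Liver Tumor CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection and segmentation of hepatocellular carcinoma in
    three-phase dynamic CT with HFS-Net, a three-stage hierarchical fusion
    of segmentation networks: Stage I liver/tumor segmentation with per-slice
    tumor size estimation, Stage II size-adaptive routing of tumor instances
    to a small-tumor (dynamic-phase DenseU-Net) or large-tumor
    (portal-venous U-Net) branch, and Stage III 3D fusion of the image and
    all sub-model outputs. Includes a synthetic three-phase CT phantom
    generator with ground-truth lesion instances, a compact deterministic
    CPU training engine (2D U-Net, 2D DenseU-Net, 3D U-Net with cross
    entropy, dice, focal and median-frequency-balanced losses), NIfTI
    preprocessing (in-plane resampling to 1.4 mm/px, Z-axis phase
    alignment, dynamic channel stacking), and the full evaluation protocol:
    dice per case and dice global, instance detection at overlap threshold
    theta across four granularities, maximum-tumor-diameter error, and
    size/tumor-count stratified reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
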