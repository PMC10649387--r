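Package: melascan
Title: Dermoscopic Melanoma Detection Toolkit: Denoising, Maximum-Entropy
    Segmentation, Radiomics Features, SVM and CNN Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested toolkit for melanoma screening pipelines on
    dermoscopy-like images: a denoising filter bank (median, Gaussian,
    bilateral, non-local means, block-matching 3D) scored with image-quality
    metrics (MSE, PSNR, SSIM, UQI), hair removal, maximum-entropy (Kapur)
    lesion segmentation with morphological refinement, first-order, GLCM,
    GLSZM and geometric feature extraction, RBF-kernel SVM classification
    with confusion-matrix evaluation, declarative CNN architecture
    specifications with analytic shape and parameter verification, a small
    CNN training engine with Grad-CAM, and seeded synthetic-lesion
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
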