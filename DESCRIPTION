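Package: hsivigor
Title: Seed Vigor Prediction from Hyperspectral Images with
    Wavelength-Attention Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for predicting seed vigor (viable versus
    non-viable) from hyperspectral reflectance cubes. Covers black/white
    reference reflectance correction, seed segmentation on dark-board
    scenes, mean-spectrum extraction, the classical chemometric
    preprocessing transforms (mean centering, moving average, SNV, MSC,
    Savitzky-Golay smoothing and derivatives, wavelet denoising), and a
    compact residual network classifier with a wavelength-attention
    channel module trained under focal loss to handle class imbalance.
    Includes a synthetic hyperspectral seed-scene generator with known
    ground truth, Grad-CAM and t-SNE interpretation utilities, and an
    attention-recovery benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rtsne,
    cluster,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
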