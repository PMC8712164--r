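Package: osteotex
Title: Texture-Based Classification of Bone Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An image-analysis pipeline for classifying bone radiographs as
    cancerous or healthy from texture statistics. Implements 3x3 median
    denoising and unsharp-mask sharpening, Canny/Sobel/Prewitt edge detection
    with region-of-interest extraction from the largest connected edge
    component, a nine-feature texture descriptor (four gray-level
    co-occurrence matrix statistics, histogram skewness, Shannon entropy and
    its standard-deviation-weighted product, a Gini inequality index of the
    Hough line accumulator, and a histogram-of-oriented-gradients block),
    linear support-vector-machine and random-forest classifiers with
    stratified k-fold cross-validation, and a synthetic bone-phantom
    generator for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jpeg,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
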