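Package: spikeseg
Title: Texture-Based Spike Segmentation, Detection Evaluation and Phenotyping
    for Greenhouse Cereal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and segmenting grain spikes (ears) in
    greenhouse RGB images of cereal plants. Implements a shallow
    neural-network pixel classifier built on Haar wavelet preprocessing,
    Laws 3x3 texture-energy features and multiscale Frangi vesselness
    post-filtering to suppress elongated leaf- and tiller-edge false
    positives; the standard object-detection and segmentation evaluation
    stack (IoU box matching, PASCAL-VOC 11-point and COCO-style average
    precision, Dice and Jaccard scores, category-stratified reports);
    dataset-preparation utilities (train/test splitting, fixed-size frame
    tiling, spike/background frame balancing, paired augmentation);
    readers and writers for PASCAL-VOC XML and YOLO box annotations and
    binary mask images; a registry of 70 per-spike shape, color and
    texture descriptors; and a seeded synthetic greenhouse-scene generator
    that produces images with exact ground-truth boxes and masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    nnet,
    png,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
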