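Package: agrinet
Title: Lightweight Attention Encoder-Decoder Networks for Crop
    Identification in Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pixel-level identification of winter wheat and winter canola in
    10-band multispectral satellite imagery with a lightweight attention-based
    encoder-decoder network (ShuffleNet v2 channel-shuffle encoder, atrous
    spatial pyramid pooling, and a convolutional block attention module).
    Provides the full pipeline: band screening, bilinear resampling and
    percentage linear stretching of Sentinel-2 rasters; 512x512 tiling with
    crop-coverage filtering and random train/validation splits; network
    construction and training (multi-class cross-entropy, Adam, polynomial
    learning-rate decay, on-the-fly augmentation) implemented natively in R;
    confusion-matrix evaluation (mIoU, overall accuracy, recall); a
    per-convolution parameter and FLOP profiler for model-complexity
    accounting; and a synthetic-scene generator for reproducible end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
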