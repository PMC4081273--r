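Package: microimage
Title: Compact Image Processing Toolkit with Synthetic Benchmark Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained suite of classic 2-D image processing
    algorithms written in base R: a strict sample-type contract (8-bit
    and unit-range float images), binary PNM input/output with lazily
    loaded image collections, rasterization primitives, Gaussian and
    rank filtering, Canny edge detection, adaptive local thresholding,
    ORB binary features with brute-force Hamming matching, planar
    geometric transforms with RANSAC estimation and inverse-mapping
    warps, line and circle Hough transforms, connected-component
    labeling with region properties, and line-profile sampling.  Three
    end-to-end pipelines (coin-style particle measurement, feature-based
    panorama registration, and crack-front tracking in drying-drop image
    stacks) run entirely on the package's own synthetic scene
    generators, which carry ground truth for every object they draw.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
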