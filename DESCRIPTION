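Package: fdbseg
Title: Fingerprint Segmentation by Factorized Directional Bandpass Filtering
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Region-of-interest segmentation for fingerprint images using a
    factorized directional bandpass (FDB) transform. A bank of directional
    Hilbert Butterworth bandpass (DHBB) filters extracts the oriented
    oscillatory ridge texture in an analysis / soft-threshold / synthesis
    scheme; the resulting feature image is binarized adaptively and refined by
    a two-scale block morphology, largest connected component selection and
    convex hull to give the region of interest. Includes the pixelwise
    segmentation error metric, dataset evaluation and grid-search parameter
    training, a synthetic fingerprint generator with exact ground truth for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, png, tiff, yaml, igraph
Suggests: testthat (>= 3.0.0), mgcv, withr
Config/testthat/edition: 3
biocViews: Software, Segmentation, Visualization
RoxygenNote: 7.3.3
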