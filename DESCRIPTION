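Package: nasemg
Title: Nasal Vowel Detection from Surface EMG with RT-MRI Derived Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for detecting nasal vowels from surface
    electromyography (EMG) of the face and neck, using velum-aperture
    information extracted from real-time MRI image sequences as ground
    truth. Covers velum-area extraction by seeded spatiotemporal region
    growing, cross-modal alignment of the MRI and EMG recordings by
    dynamic time warping of their audio tracks, segmentation of the
    warped aperture curve into nasal and non-nasal zones with a
    mean-plus-half-SD threshold and a mirrored-angle boundary extension,
    frame-level temporal feature extraction, SVM classification under
    stratified 10-fold cross-validation, zone-majority classification,
    and mutual-information analysis. A synthetic-data generator with
    known ground truth makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    e1071,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
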