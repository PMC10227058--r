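Package: awakeretina
Title: Analysis Toolkit for High-Resolution Retinal Imaging in Awake Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis stack for high-resolution retinal imaging of
    awake, head-fixed mice. Provides pupil segmentation and beam-clipping
    geometry for optical-axis stability assessment, blink detection and
    template-based gaze tracking for scanning laser ophthalmoscope (SLO)
    video, strip-based motion correction for adaptive optics SLO (AOSLO)
    frames, extraction and spectral analysis of high-frequency ocular
    micro-tremor from 15 kHz line-scan space-time images, Radon-transform
    single-cell blood velocimetry with vessel diameter, flow and
    flow-diameter power-law modelling, graph-based dynamic-programming
    segmentation of OCT retinal boundaries with total-retinal-thickness
    mapping, and quadrature rotary-encoder decoding of locomotion. Every
    stage is driven by a synthetic-data generator with known ground truth,
    so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
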