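Package: wavetrack
Title: Quantification of Actin Waves in Developing Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify actin waves (AWs) in time-lapse fluorescence
    movies of developing neurons and myosin puncta in STED nanoscopy images.
    Includes phase-congruency line-feature detection of neurites, geodesic
    (minimum-path) neurite-length measurement, seeded tracking of the soma,
    neurite hillock, neurite edge and travelling waves, kymograph
    construction, wave velocity and frequency estimation, growth-cone
    "pulling" event detection, area morphometry, line-scan extraction and
    half-maximum alignment, puncta density quantification with actin
    normalization, and the group-comparison statistics used for such data.
    A synthetic-data generator renders movies and STED-like scenes with full
    ground truth so that every stage is verifiable without raw microscopy
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    mgcv,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
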