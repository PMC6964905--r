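Package: remodelkit
Title: Quantification of Cell-Driven Extracellular Matrix Remodeling in
    Collagen-Matrigel Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipelines for measuring how embedded cells
    remodel fibrous collagen-Matrigel hydrogels: fiber-network morphometry
    (mean fiber length, persistence length, pore size), FFT orientation-tensor
    anisotropy of fiber alignment, collagen densification in control, alignment
    and peri-cellular "doughnut" regions, dye-quenched (DQ) collagen
    degradation volumetry, focal-adhesion detection and sizing in 2D and 3D,
    and time-lapse cell tracking with accumulated-distance and speed
    statistics. A ground-truthed synthetic microscopy image generator makes
    every pipeline testable end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
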