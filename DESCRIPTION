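Package: petctlabel
Title: Semi-Automatic Labeling of Tumor Lesions in PET/CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building deep-learning training labels from paired
    positron emission tomography (PET) and computed tomography (CT) slices.
    The pipeline enlarges the low-resolution PET slice to CT size by bilinear
    interpolation, enhances the low-gray uptake range with a piecewise linear
    gray transform, registers PET to CT with a closed-form six-parameter
    affine least-squares fit to user-chosen landmark pairs (optionally after
    an outer-frame pre-alignment), fuses the registered pair by weighted
    combination of sym8 wavelet coefficients, grows the lesion region from a
    single professional's click with an 8-neighborhood seeded region grower,
    and exports polygon and bounding-box annotations as JSON. A synthetic
    phantom generator with known lesion masks, misalignment and landmarks
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
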