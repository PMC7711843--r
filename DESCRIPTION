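Package: tomodock
Title: Quantification of Vesicle Docking Sites in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection, measurement and classification of SUV-GUV vesicle
    docking sites in cryo-electron tomograms of reconstituted SNARE-mediated
    fusion systems. Provides a synthetic tomogram generator (membrane phantoms
    with missing-wedge filtering and noise), MRC volume and landmark-table
    input/output, spherical-vesicle detection, oriented subtomogram
    extraction, membrane-separation and contact-interface measurement,
    protein-density landmark detection, junction morphology classification
    (clustered / intermediate / ring-like), correlation statistics,
    landmark-based class averaging, and biophysical calculators for
    reconstitution copy numbers, SNAREpin bridging spans and steric exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
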