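Package: angiomorph
Title: Morphometric Analysis of Endothelial Tube Formation and Fibrin
    Bead Sprouting Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects microcarrier beads and pseudo-capillary networks in
    phase-contrast micrographs of in vitro angiogenesis assays, models
    them as vectorial objects (spheres, junctions, extremities, branches,
    segments, anchorage junctions, isolated elements and meshes) and
    computes the standard morphometric measurements (total length, total
    segment length, junction counts, mesh areas) per image or per bead.
    Includes a synthetic phase-contrast scene renderer with exact ground
    truth for validation, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
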