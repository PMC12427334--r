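Package: pigloop
Title: Dorsal-Mask Morphometrics, Weight Estimation, Precision Feeding
    and Carbon Footprint Accounting for Pig Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the downstream half of a camera-based precision
    pig-farming loop: morphometric feature extraction (relative projection
    area, contour perimeter, body length and width from the minimum-area
    rotated rectangle, and least-squares ellipse eccentricity) from binary
    dorsal segmentation masks; random-forest live-weight estimation with
    animal-level train/test splits and pig-level cross-validated grid
    search; growth-stage ration tables with dynamic precision-feeding
    adjustments; and a cradle-to-farm-gate life-cycle assessment of the
    carbon footprint (feed production, transport, enteric fermentation,
    energy use, manure management) normalised per kilogram of live weight.
    Ships a synthetic-data module (superellipse silhouettes, growth
    cohorts, farm activity ledgers) with known ground truth so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
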