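Package: vitisense
Title: Proximal Canopy Sensing Analytics for Vineyard Vigor Mapping
Version: 0.1.0
Authors@R:
    person("Vitisense", "Developers", email = "dev@vitisense.example", role = c("aut", "cre"))
Description: Computational chain for tractor-mounted proximal canopy sensing
    of trellised vineyards. Segments side-view RGB frames into vegetation and
    background with a two-class Jenks natural-breaks classifier to produce a
    0-1000 Canopy Index (CI), slices the canopy wall into 15 CI / 16 surface
    temperature sectors from the sensor geometry, derives vertical-profile
    indices (center of gravity, moment of inertia, background-corrected
    canopy temperature), computes point-quadrat ground-truth metrics (leaf
    layer number, canopy gaps, interior leaves) and canopy porosity, fits
    CI-to-ground-truth calibrations, and exports geo-referenced thematic
    maps from survey logs. A coupled synthetic-vineyard generator emulates
    images, point-quadrat insertions and survey tracks from one virtual
    canopy occupancy model so the whole pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    sp,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
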