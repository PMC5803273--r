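Package: lcptools
Title: SAXS Indexing and Minimal-Surface Geometry of Lipidic Mesophases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 1-D small-angle X-ray scattering (SAXS)
    profiles of lyotropic lipid mesophases. Detects Bragg peaks, indexes them
    against bicontinuous cubic (Ia3d, Pn3m, Im3m), lamellar and inverse
    hexagonal reflection series, fits lattice parameters, and resolves
    two-phase coexistence. Converts lattice parameter and sample composition
    into water-channel geometry through triply periodic minimal surface
    relations, assembles hydration-resolved phase diagrams, detects re-entrant
    order-to-order transitions, and includes a seeded synthetic SAXS generator
    with ground truth plus small crystallographic calculators (unit-cell
    volume, Matthews coefficient, solvent fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
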