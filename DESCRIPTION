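Package: npcquant
Title: Nuclear Pore Complex Quantification from Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether nuclear pore complex (NPC) numbers
    differ between cell states using single-molecule localization
    microscopy (STORM/SMLM). Provides localization-table input/output,
    cross-correlation drift correction, PSF-width quality filtering, a
    native HDBSCAN implementation for extracting individual NPCs from
    localization clouds, Monte-Carlo tuning of the minimum cluster size,
    per-nucleus pore statistics (NPC density, localization density,
    localizations per pore, pore diameter) and two-group comparisons.
    Also quantifies FRAP recovery kinetics (exponential association fits,
    half-times, Axelrod-style diffusion coefficients) and
    nuclear-to-cytoplasmic intensity ratios. A synthetic-data module
    generates blinking-emitter localization tables with known ground
    truth, FRAP traces and intensity images so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    mgcv,
    yaml,
    tiff,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
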