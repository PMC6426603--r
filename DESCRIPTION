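Package: swarmotility
Title: Single-Cell Motility, Motor, and Signaling Analysis for Swarming Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify how swarming Escherichia coli remodels its
    chemotaxis behavior. Provides seeded generators for pseudo-2D
    run-and-tumble swimming movies, tethered-bead flagellar motor traces,
    chloramphenicol-chase protein decay courses, and two-channel fluorescence
    scenes; a single-particle tracking pipeline (background subtraction,
    radial-symmetry subpixel detection with false-discovery-rate control,
    motion-model linking); trajectory analysis (diffusion-based motile
    classification, run/tumble segmentation, tumble bias, tumble-excluded
    swimming speed); bead-trace analysis (signed rotation frequency, reversal
    counting, torque from a bead drag model); Western-blot and per-cell
    fluorescence quantification; a trajectory-weighted one-way ANOVA with a
    permutation null; and a Goldbeter-Koshland futile-cycle model linking
    CheZ phosphatase levels to tumble bias through zero-order
    ultrasensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
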