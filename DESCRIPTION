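Package: retinatune
Title: Spectral, Mosaic and Eyeshine Analysis of Graded Opsin Co-Expression in Butterfly Retinas
Version: 0.1.0
Authors@R:
    person("Retina", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to infer graded opsin co-expression across a compound-eye
    retina from three complementary data streams: intracellular recordings
    (Hill/Naka-Rushton intensity-response fits, reverse Hill transformation of
    spectral and polarization scans, isolation of colour-opponent units by
    selective chromatic adaptation), immunolabelled retinal sections
    (ommatidial typing over the 15-type space spanned by U, B, L, UL and BL
    photoreceptor states, with strip-density profiles along the dorso-ventral
    axis), and hyperspectral eyeshine image stacks (background subtraction,
    RGB mapping, lattice spot detection and red/non-red/dark classification
    with elevation fraction profiles). A seeded synthetic-data generator
    emulates all three data streams with known ground truth so every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
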