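Package: runtumble
Title: Physics-Grounded Analysis of Bacterial Run-and-Tumble Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of swimming behaviour in flagellated bacteria observed
    by video microscopy, grounded in the Brownian hydrodynamics of prolate
    ellipsoids of revolution. Provides Perrin friction factors and Einstein
    diffusivities for spheroidal cells, probability-threshold discrimination
    of motile from non-motile cells and segmentation of tracks into runs and
    tumbles, resistive-force-theory and power-scaling forward models linking
    cell aspect ratio to swimming speed and tumble angle, mean-square
    angular deviation time constants, two independent population diffusivity
    estimators (run-and-tumble statistics and Taylor's dispersion equation),
    and a ground-truth simulator of run-and-tumble trajectories with an
    optional grayscale frame renderer, particle detector and overlap-based
    tracker so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
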