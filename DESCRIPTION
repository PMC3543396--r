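Package: ivmclean
Title: Motion-Artifact Removal for Two-Photon Intravital Microscopy Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection and removal of motion-artifact frames from
    two-photon intravital microscopy time-lapse recordings. Frames are scored
    by mean squared difference against a reference frame on a designated
    stable reference channel (typically blood vessels), with references either
    fixed or generated automatically as rolling average-intensity projections.
    High-scoring frames are rejected by percentile and n-neighbor relative
    maximum filters (optionally applied twice to catch consecutive artifacts),
    the surviving sequence is registered frame-to-frame (translation, rigid,
    scaled rotation or affine), and post-processing utilities provide channel
    bleed-through subtraction, grouped intensity projections, causal Kalman
    stack denoising, and removal-aware timestamp and scale-bar overlays.
    Includes a seeded synthetic video generator with planted, ground-truth
    labelled artifacts so every pipeline stage can be validated without
    animal recordings.
License: MIT
Encoding: UTF-8
Imports:
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
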