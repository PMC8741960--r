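Package: ivmflow
Title: Microvascular Perfusion Quantification from Intravital Video Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies microvascular tissue perfusion from intravital
    trans-illumination video microscopy of skeletal muscle. Builds
    sum-of-absolute-differences (SAD) motion images from 16-bit video
    stacks, registers repeated observations of the same field of view,
    segments the actively perfused vessel structure, overlays a 10 x 10
    line grid, and counts grid-vessel intersections that carry red-blood-
    cell flow (the perfusion index). Includes a seeded synthetic
    intravital-video generator with full ground truth for validation,
    longitudinal statistics (percent change versus baseline, one-way
    ANOVA with Dunnett many-to-one correction), and a deterministic
    calculator for miniaturized hollow-fiber dialyzer geometry and
    extracorporeal volume bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    igraph,
    png
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
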