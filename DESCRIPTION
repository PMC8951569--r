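Package: corotrack
Title: Dye-Free Tracking of Coronary Arteries in Cine-Angiography
Version: 0.1.0
Authors@R:
    person("corotrack", "developers", email = "corotrack@example.org",
           role = c("aut", "cre"))
Description: Tools to locate coronary arteries in cine-angiography frames that
    contain no contrast dye. Contrasted "template" frames are segmented with a
    multi-scale Hessian (Frangi) vesselness filter and morphological cleanup;
    every dye-free frame is then associated with the most similar template by
    normalized cross-correlation and the template's vessel contour is
    transferred onto it. Includes a minimal DICOM reader/writer for
    uncompressed grayscale cine loops, automatic contrast-bolus window
    detection with manual override, a ground-truthed synthetic cine-angiogram
    simulator (curvature, width variation, stenoses, cardiac motion, bolus
    dynamics, noise), evaluation metrics (Dice overlap, phase-assignment
    accuracy, bolus-window error), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
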