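Package: codseg
Title: Automated Change-of-Direction Event Detection from Full-Body
    Inertial Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects change-of-direction (COD) events in V-cut agility
    trials recorded with full-body inertial motion capture. Trunk
    horizontal speed is low-pass filtered with a zero-phase Butterworth
    filter, prominence-qualified local minima mark candidate cuts, and
    heel-strike / toe-off transitions in the binary foot-contact channels
    within a search region around each minimum yield the initial frame
    (IF, heel strike of the penultimate foot contact) and final frame
    (FF, toe off of the final foot contact) of every cut. Includes
    readers for MVNX and tabular trial files, manual-label ingestion,
    automatic-vs-manual agreement statistics (signed-difference
    summaries, average precision at frame thresholds, Bland-Altman
    limits of agreement, cutting-time correlation, RMSE), a stratified
    split plus grid-search parameter tuner, a synthetic V-cut trial
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
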