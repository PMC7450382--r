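Package: figcopy
Title: Quantitative Analysis of Digital Pen Data from Figure-Copying Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing digital-pen recordings of a simplified
    complex-figure copying task. Ingests timestamped pen-event logs from a
    tablet, segments them into strokes in physically calibrated coordinates,
    and computes stroke-kinematic features (counts, projected lengths,
    long/short classification by one-dimensional k-means++, transition and
    elapsed times), spatial-arrangement features (whole and skeleton bounding
    areas, centre of mass, closing-in ratio of input in the perceptual space),
    and shape similarity between drawing and stimulus by two-dimensional
    normalized cross-correlation. Includes the canonical eight-component
    stimulus template with its 0-16 scoring arithmetic, pseudocolour
    stroke-order rendering, a synthetic session simulator with controllable
    impairment phenotypes, and a nonparametric group-comparison harness
    (Kruskal-Wallis, pairwise Mann-Whitney with Dunn-Sidak correction).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
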