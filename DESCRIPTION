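Package: nodulekit
Title: Pulmonary Nodule Detection from CT Slices with Swarm-Tuned
    Recurrent Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computer-aided detection pipeline for pulmonary
    nodules in 2-D CT slices. Provides morphological lung-field (lobe)
    segmentation and region-of-interest masking, fuzzy C-means nodule
    segmentation with an optional per-pixel backbone feature bank,
    statistical-moment and local ternary pattern (LTP) / local optimal
    oriented pattern (LOOP) texture descriptors, a bidirectional LSTM
    classifier whose weights are tuned by a cnidaria-herd swarm optimizer
    (a jellyfish time-control phase schedule combined with krill-style
    induced movement), and a synthetic CT phantom generator with ground
    truth so that every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
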