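Package: mptexture
Title: Texture-Based Tissue Classification for Label-Free Multiphoton Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Observer-independent discrimination of brain tumor versus nontumor
    tissue from label-free multiphoton microscopy images (CARS, TPEF, SHG).
    Computes 13 first- and second-order (gray-level co-occurrence matrix)
    texture parameters per channel and field of view after min-max
    normalization, classifies fields of view with a two-class linear
    discriminant yielding posterior tumor probabilities, aggregates fields of
    view into per-sample diagnostic ratings by the median, renders tiled
    blue-to-red probability maps for tumor border delineation, and reports
    sensitivity, specificity and correct rates. Includes a seeded synthetic
    image generator emulating the morphochemical contrasts of the three
    channels so the whole pipeline is testable without patient data.
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
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
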