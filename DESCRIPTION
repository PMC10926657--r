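Package: otoshape
Title: Otolith Outline Morphometrics and Shape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Outline-based morphometric analysis of fish otoliths
    (sagittae, lapilli and asterisci): contour extraction from binarized
    grayscale images, size measures and dimensionless shape indices,
    wavelet and elliptic Fourier shape descriptors with reconstruction
    diagnostics, allometric (fish-length) adjustment of coefficients,
    distance-based permutation tests and linear discriminant analysis
    for side, sex and size-class discrimination, and group mean-shape
    reconstruction. Includes a synthetic otolith-contour generator so
    the whole pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    EBImage,
    png,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    vegan,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
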