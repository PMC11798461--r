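Package: sphtex
Title: Spherical Texture Descriptors for Segmented Microscopy Objects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rotationally invariant, scale-normalized texture descriptors for
    segmented objects in 2D and 3D microscopy images. Each labeled object is
    resampled to a standard cube, projected to an angular mean-intensity map
    by casting rays from its center (a spherical projection in 3D, a circular
    one in 2D), normalized to zero mean and unit variance, and decomposed into
    a spherical-harmonics (3D) or Fourier (2D) power spectrum. Per-degree
    power is mapped to approximate angular wavelengths via the Jeans relation
    and integrated into 20 log2-spaced wavelength bins, yielding a compact
    descriptor of how much intensity variance lives at each angular scale.
    Also provides polarization (peak-direction) extraction with optional
    band-pass filtering, a Perlin-noise synthetic data generator for
    validation, TIFF input, CSV/JSON descriptor export, and a command-line
    interface for batch extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    tiff,
    pracma,
    readr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
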