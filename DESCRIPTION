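Package: carbscreen
Title: Carbonization Screening of Carbonaceous Matter from Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess the thermal maturity (carbonization) of disordered
    carbonaceous matter such as kerogen from first-order Raman spectra.
    Implements the constrained five-band (G, D1-D4) Lorentzian/Gaussian
    decomposition, a fit-free graphical estimation of the R1 ratio and
    FWHM-D1, and a carbonization-continuum classification that flags altered
    and partially graphitized samples and selects best-preserved candidates
    for molecular biosignature studies. Companion maturity indices (atomic
    H/C from elemental analysis, 13C NMR aromaticity by 90 ppm split
    integration, mean polyaromatic layer length La from skeletonized HRTEM
    lattice-fringe images) and seeded synthetic-data generators for all
    modalities are included, along with a transcribed reference table of 17
    Precambrian and Phanerozoic cherts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
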