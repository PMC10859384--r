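Package: mpdfir
Title: Microplastic Detection from O-PTIR Spectra and Discrete-Frequency IR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and quantifying nylon microplastic particles
    from optical photothermal infrared (O-PTIR) point spectra and
    discrete-frequency infrared (DFIR) image stacks. Implements per-spectrum
    preprocessing (standard normal variate, Savitzky-Golay smoothing,
    asymmetric least-squares baseline correction, min-max normalization),
    Pearson-correlation particle identification, a linear support-vector
    discriminator with coefficient-based wavenumber selection, pixel-wise
    classification of DFIR stacks with per-particle majority voting, particle
    morphometry, and whole-filter quantification by subsample extrapolation.
    Seeded synthetic-data generators for class-structured spectra, particle
    scenes and filter experiments make every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    e1071,
    signal,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
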