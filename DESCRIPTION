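Package: spectrachart
Title: Static SVG Charts for Mass Spectrometry, NMR and IR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders spectra from mass spectrometry, one- and two-dimensional
    NMR, infrared spectroscopy and general time series to standalone SVG
    documents, following the de facto layout conventions of each technique
    (reversed ppm and wavenumber axes, impulse plots for mass spectra,
    transmittance valleys for IR). Large traces are downsampled by
    extremum-preserving per-pixel binning that keeps the original minimum or
    maximum intensity point in each pixel-width bin. Supports multi-series
    overlays with a legend, automatic signal labels at local maxima, and a
    group-based annotation framework whose tooltips render key-value pairs
    and 2D molecule depictions parsed from MDL Molfile V2000 text by an
    internal fixed-column parser. Includes seeded synthetic-spectrum and
    molfile generators and a command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    optparse,
    ChemmineR
Config/testthat/edition: 3
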