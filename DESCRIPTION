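Package: xpsprot
Title: Quantification of Immobilized Protein Surface Density from XPS C1s Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the X-ray photoelectron spectroscopy (XPS) C1s
    spectrum of a protein from its amino-acid sequence by enumerating the
    carbon chemical environments of every residue, and estimates the surface
    density of a protein immobilized on a polymer substrate by fitting the
    measured C1s spectrum as a two-component linear mixture of the substrate
    spectrum and the simulated protein spectrum. Includes Shirley background
    subtraction, binding-energy calibration, an independent elemental (N/C)
    coverage estimator, and a seeded synthetic-measurement generator for
    validation. Targets poly(epsilon-caprolactone) nanofiber substrates with
    or without a carboxyl-rich plasma-polymer coating, but the chemistry
    tables and component models are fully user-overridable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
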