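Package: powderspec
Title: Powder Infrared and Terahertz Absorption from Gamma-Point Phonons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the frequency-dependent complex permittivity of a
    crystal from gamma-point phonon frequencies, mode eigenvectors and Born
    effective charges (a Lorentz-oscillator model), applies the long-wavelength
    non-analytic correction to obtain LO frequencies, homogenizes the
    permittivity with effective-medium theory (Maxwell-Garnett, Bruggeman and
    averaged-permittivity mixing rules) for spherical, plate-like, needle-like
    and ellipsoidal particles dispersed in a non-absorbing matrix, and predicts
    the infrared/terahertz absorption and molar absorption spectra of the
    resulting powder. Includes a documented text format for phonon data, a
    synthetic-crystal generator, built-in oscillator-table models for several
    reference materials, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
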