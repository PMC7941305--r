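Package: saxskit
Title: Simulation, Reduction and Validation of Small-Angle X-Ray Scattering Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for small-angle X-ray scattering (SAXS)
    that closes the loop from atomic coordinates to simulated two-dimensional
    photon-counting detector images, back to reduced one-dimensional
    scattering curves, and on to statistical validation and model-free
    structural parameters.  Scattering intensities are computed by the Debye
    sum with optional wavelength-dependent anomalous dispersion corrections
    (f', f''), detector images are simulated as independent Poisson draws
    from a physical expected-count model, radial averaging uses Poisson
    error estimates with Anscombe-transform robust outlier rejection, and
    curve pairs are compared with the reduced chi-square, longest-run
    correlation-map (CorMap) and Anderson-Darling statistics with exact or
    asymptotic p-values.  Real-space pair distance distribution functions
    are obtained by a direct Fourier transform with Guinier low-angle and
    power-law high-angle extrapolation, and molecular weight is estimated
    from the Porod volume and the volume of correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    pracma,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
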