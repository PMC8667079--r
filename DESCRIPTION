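Package: sliscat
Title: Scattered Light Imaging Scatterometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Scattered Light Imaging (SLI)
    scatterometry of unstained histological brain sections. Converts the
    series of camera images recorded while a kernel of LEDs scans an
    illumination display into per-pixel scattering patterns, computes
    azimuthal line profiles by radial integration with bilinear
    interpolation, smooths the profiles with a tanh-windowed Fourier
    low-pass filter, detects and pairs profile peaks to recover the
    in-plane directions of up to four crossing nerve-fiber bundles per
    pixel, and renders hue-coded fiber orientation maps. A forward
    phantom simulator generates synthetic measurements with ground-truth
    fiber directions for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
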