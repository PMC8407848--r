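Package: thzretrieve
Title: Hybrid Kramers-Kronig and Fabry-Perot Retrieval for Terahertz
    Reflection Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the complex refractive index of an optically thin
    layer on a known substrate from terahertz time-domain reflection
    measurements. A singly-subtractive Kramers-Kronig consistency loop
    corrects the frequency-linear phase offset caused by sample/reference
    plane misalignment and yields the layer thickness; a Fresnel/Fabry-Perot
    multilayer model is then fitted per frequency by an exhaustive
    two-dimensional scan over refractive index and extinction coefficient.
    Includes an analytic forward model and waveform generator for layered
    lossy media, a per-pixel raster-scan imaging pipeline, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
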