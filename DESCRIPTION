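Package: parvocone
Title: Spatio-Chromatic Optimisation of Primate Cone Spectral Sensitivities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational model of the primate parvocellular retina for
    predicting optimal M and L cone peak spectral sensitivities. Builds
    hyperspectral grating stimuli from fruit, leaf and Munsell-like
    reflectance spectra under a natural illuminant, with 1/f luminance
    variation and wavelength-dependent Airy-disk blur; simulates a random
    L/M cone mosaic, quantal catch, difference-of-Gaussians midget
    ganglion-cell receptive fields and red-green/luminance channel
    integration; and scores every candidate pair of peak sensitivities by
    the peak signal-to-noise ratio between the channel output and the
    reference grating. Includes an exhaustive-search harness with
    replicate statistics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
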