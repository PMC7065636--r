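Package: hsoct
Title: Hyperspectral Visible-Light OCT Simulation and Melanin Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting Mie-regime scatterers, such as retinal
    pigment epithelium melanin granules, in spectral-domain optical
    coherence tomography. Provides wavelength-dependent complex
    refractive index models for eumelanin, silicone elastomer and
    retinal tissue, a Mie series for the backscattering coefficient of
    granule populations, a paraxial chromatic model of ball-lens eye
    phantoms, a seeded synthetic SD-OCT interferogram generator, the
    27-band short-time Fourier hyperspectral reconstruction (background
    removal, k-linearization, Gaussian sub-band windows, numerical
    dispersion compensation, axial registration), and the
    watershed-binned deviation-from-mean (DFM) statistic with 3-sigma
    thresholding and depth-windowed concentration metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
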