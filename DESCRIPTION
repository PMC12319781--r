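Package: tdot
Title: Time-Domain Diffuse Optical Tomography: Simulation, Characterization, and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational stack for whole-head time-domain diffuse optical
    tomography (TD-DOT) and time-domain functional near-infrared spectroscopy
    (TD-fNIRS). Provides analytical time-resolved diffusion forward models and
    voxel-level sensitivity (Jacobian) kernels, a virtual dual-wavelength
    instrument simulator (instrument response functions, laser multiplexing,
    shot noise, phantoms, and block-design task hemodynamics), photon
    time-of-flight histogram featurization (moments, gates, deconvolution),
    the BIP, MEDPHOT and nEUROPt instrument characterization figures of merit,
    a channel-space hemodynamic pipeline (moments to absorption changes to
    oxy-/deoxyhemoglobin via the modified Beer-Lambert law, motion correction,
    superficial-signal removal), GLM inference, and moment-based volumetric
    reconstruction with Tikhonov regularization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
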