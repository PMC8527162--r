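Package: dotprops
Title: Breast and Chest-Wall Optical Properties from Frequency-Domain
    Diffuse Reflectance
Version: 0.1.0
Authors@R:
    person("Alex", "Morgan", email = "alex.morgan@example.org",
           role = c("aut", "cre"))
Description: Estimates the average absorption and reduced scattering
    coefficients of breast tissue and of the underlying chest-wall layer
    from frequency-domain diffuse reflectance measured with a hand-held
    9-source / 14-detector probe. Provides diffusion-equation forward
    models (semi-infinite closed form, analytic two-layer Green's function,
    and a 3D finite-difference solver for heterogeneous voxel phantoms),
    least-squares source/detector gain calibration, the classical
    slope-based homogeneous fit, a two-layer Nelder-Mead inverse fit, and a
    small convolutional neural network regressor trained on simulated
    two-layer photon-migration data, together with digital breast phantom
    generators and method-comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
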