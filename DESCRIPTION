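Package: gaitpress
Title: Pathological Gait Recognition from Plantar-Pressure Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising pathological gait (toe-in, toe-out and
    flat foot) from 8x8 plantar-pressure insole recordings of children, in
    both walking (dynamic) and standing (static) conditions. Includes a
    piezoresistive readout-electronics model with row/column crosstalk
    simulation and least-squares calibration, a labelled synthetic gait
    generator, One Euro filtering and sliding-window preprocessing,
    per-sensor FFT band-energy and standing-load features, PCA and
    multiclass linear discriminant reduction, an SMO-trained support vector
    machine and a small feed-forward network, and a stratified k-fold /
    leave-one-subject-out evaluation harness with the associated metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
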