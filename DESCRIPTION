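Package: photodose
Title: Light Dosimetry Planning and Simulation for LED-Array Photodynamic
    Therapy Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plans and simulates multiwell-plate photodynamic therapy (PDT)
    light treatments delivered by a pulse-width-modulated (PWM) LED array.
    Provides spectral overlap-integral efficiency and effective-light-dose
    conversion between broadband LED sources and a reference laser line,
    duty-cycle quantization and duty-to-irradiance calibration, well-plate
    layout validation and treatment-plan generation in motor steps,
    thermistor/phototransistor voltage-divider models with a PCB electrical
    budget, a radiometric model of the LED array irradiance field with
    uniformity metrics, a first-order lumped thermal model of sample heating
    with safe-exposure planning, four-parameter logistic dose-response
    fitting with EC50 extraction, and a virtual-hardware runtime simulator
    with per-well fluence accounting. All components are testable without
    hardware via a seeded synthetic-fixtures generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
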