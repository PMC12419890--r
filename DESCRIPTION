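Package: cutmech
Title: Fracture Mechanics of Thin-Sheet Cutting by Insect Mandibles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses the force required to cut thin, leaf-like
    sheets with a blade of finite sharpness. Implements the lower-bound
    cutting force Gc*t, the dimensionless sharpness number Omega =
    C*sigma_c*R/Gc and the resulting force prediction Gc*t*(1 + Omega),
    together with the measurement pipeline needed to test the model:
    decomposition of two-pass force traces into total, spacing and fracture
    forces; estimation of cutting-edge radius and wedge angle from digitized
    tip cross-sections; derivation of Young's modulus, tensile strength and
    pure-shear tearing energy from stress-strain records; and allometric
    power-law fits of blade wear against body mass. A synthetic-data
    generator produces force traces, contours, stress-strain curves and
    worker populations with known ground truth so that every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
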