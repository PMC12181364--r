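Package: sweclip
Title: Semi-Automated Analysis of Shear Wave Elastography Clips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of ultrasound shear wave elastography (SWE)
    clips in muscle tissue. Locates the color elastogram inside each frame via
    the colored frame line, calibrates physical scale from the on-screen
    measurement bar, inverts the 50%-opacity color overlay back to Young's
    modulus in kPa, and computes per-frame and per-clip region-of-interest
    statistics over a hand-drawn rectangle or a tiling of 4 x 4 mm squares.
    Includes conversions among Young's modulus, shear modulus and shear wave
    velocity, a validation-statistics toolkit (Spearman correlation, the full
    Bland-Altman workflow with proportional-bias regression and a
    log-transformed branch, and an exact agreement hypothesis test based on the
    noncentral t distribution), and a synthetic clip renderer that produces
    ground-truth fixtures with the same screen layout so every pipeline stage
    can be tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
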