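Package: magrule
Title: Physical Model of the Magnification Rule for HER2 Immunohistochemistry Scoring
Version: 0.1.0
Authors@R: person("Targos", "Morphometry", email = "morphometry@example.org",
    role = c("aut", "cre"))
Description: Simulation and morphometry toolkit for the optical basis of
    semi-quantitative HER2 immunohistochemistry scoring. Renders synthetic
    tumor-cell images with membranous DAB precipitates of known width and
    optical density under a Beer-Lambert stain-mixing model, separates stains
    by color deconvolution (Ruifrok-Johnston), measures precipitate width as
    the full width at half maximum of perpendicular line profiles, relates
    widths to diffraction-limited microscope objective resolution via Abbe's
    law, classifies specimens into IHC scores 0/1+/2+/3+ through
    optical-resolution windows, and reproduces cohort-level statistics
    (Welch tests, width-intensity correlation, ISH subgroup comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
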