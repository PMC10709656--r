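Package: contactguidance
Title: Quantifying Cell Contact Guidance on Microgrooved Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for contact-guidance experiments in which
    fibroblasts are cultured on ridge/groove substrates of varying lateral
    widths and groove depths. Computes static morphology metrics from cell
    outlines (moment-matched ellipse fits, aspect ratio, alignment angle,
    elongated/aligned population fractions, alignment histograms), dynamic
    migration metrics from nucleus tracks (directional orientation, angular
    displacement distributions, speeds and their groove-axis decomposition,
    directional displacement and directionality ratios, mean squared
    displacement, velocity autocorrelation), nonparametric group statistics
    (Kruskal-Wallis with Dunn-Sidak post hoc) and multiple linear regression
    of population fractions on topographic dimensions, and a filopodia
    bending-angle model. Includes a seeded anisotropic persistent random walk
    and outline generator that emulates the statistical structure of such
    experiments for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    jsonlite
Config/testthat/edition: 3
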