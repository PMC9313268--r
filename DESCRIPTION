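Package: opticlear
Title: Quantitative Transparency Assessment for Optically Cleared Tissue
Version: 0.1.0
Authors@R:
    person("opticlear", "developers", email = "opticlear@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the transparency of optically cleared tissue
    from paired bright-field transmitted-light images using the Beer-Lambert
    law, following a randomized region-sampling protocol with hierarchical
    averaging (regions within runs within images within samples).  Includes
    one-way ANOVA with Bonferroni post-tests for comparing clearing
    conditions, a light-sheet image-stack processing chain (3x3 median
    filtering, Fourier-notch stripe-artifact removal, linear contrast
    adjustment, maximum-intensity projection, volume export), a synthetic
    phantom generator with known ground truth for validation, and a command
    line interface covering simulation, measurement, comparison and stack
    processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
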