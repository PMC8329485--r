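Package: starchtrace
Title: Starch-Source Authentication of Beer by Non-Targeted Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the starch source (barley, wheat, corn, rice)
    used in brewing from non-targeted mass-spectrometry data. Implements exact
    monoisotopic mass arithmetic and molecular-formula annotation in the
    CHNOSPCl space (exhaustive enumeration plus mass-difference network
    propagation), mass alignment of direct-infusion peak lists into feature
    matrices, occurrence filtering, LOWESS quality-control drift correction and
    scaling, a from-scratch multi-class OPLS-DA estimator with cross-validated
    Q2, CV-ANOVA and Hotelling's T2 diagnostics, percentile-based marker
    extraction with van Krevelen characterization, mass-difference and MS2
    spectral-similarity networks, cross-platform feature matching, and a
    synthetic cohort generator with planted marker chemistry for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
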