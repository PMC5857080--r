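Package: rsmbe
Title: Response Surface Optimisation and Biodegradation Efficiency for
    Alkane-Degrading Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage statistical optimisation of n-alkane biodegradation
    by bacterial cultures: Plackett-Burman screening and central composite
    designs with coded/actual factor mapping, second-order (quadratic)
    response-surface regression in coded units with full ANOVA, lack-of-fit
    and PRESS diagnostics, exact box-constrained maximisation of the fitted
    surface with single-response desirability, and GC-FID biodegradation
    efficiency from chromatogram peak tables matched to an n-alkane
    standard ladder. Ships the central composite design/response tables for
    two Antarctic diesel-degrading isolates as plain-text fixtures, plus
    seeded generators for synthetic design responses and chromatograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
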