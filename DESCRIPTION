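Package: fossagii
Title: Transseptal Puncture Site Scoring by Catheter Isotropy on Fossa
    Ovalis Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plans and evaluates transseptal puncture (TSP) sites on
    triangulated fossa ovalis (FO) meshes.  A constant-curvature continuum
    catheter pivoting at each candidate site is scored by the global
    isotropy index (the ratio of the smallest to the largest singular value
    of the catheter Jacobian), aggregated over the reachable left-atrial
    workspace; the package maps unreachable left-atrial regions, and
    analyses operator puncture performance with Euclidean distance metrics,
    Pearson correlations against procedural time, Bland-Altman agreement of
    caliper versus mesh measurements, Kruskal-Wallis inter-rater tests and
    Likert questionnaire descriptives.  A synthetic-data generator with
    known ground truth (parametric biatrial geometry, operator cohorts,
    measurement pairs, questionnaire tables) supports parameter-recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
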