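Package: nmrmetab
Title: Serum 1H-NMR Metabolic Profiling of Hypertensive Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for one-dimensional 1H-NMR serum
    metabolomics of the spontaneously hypertensive rat model: synthetic
    multi-group spectrum generation with Lorentzian multiplets, water-region
    exclusion, adaptive spectral binning, probabilistic quotient
    normalization and pareto scaling, PCA and OPLS-DA with repeated twofold
    cross-validated Q2, permutation validation and VIP scores, univariate
    biomarker selection with Benjamini-Hochberg correction and a
    fold-change reversal rule, and pathway over-representation plus
    topology-impact screening over packaged pathway graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
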