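Package: antioxscreen
Title: Dual Cell-Free and Cell-Based Antioxidant Screening Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microplate antioxidant screening campaigns
    that combine cell-free chemistry (Folin-Ciocalteu total phenolic content
    against gallic acid standards; FRAP ferric-reducing power against Trolox
    standards, with kinetic plateau detection) with cell-based endpoints
    (kinetic DCF fluorescence for intracellular reactive oxygen species in
    AAPH-stressed Caco-2 cells; Griess nitrite for nitric oxide in
    LPS-stimulated RAW264.7 macrophages; resazurin viability with a
    cytotoxicity gate). Provides plate-map and long-format measurement
    readers, standard-curve calibration, background correction and
    trapezoidal AUC normalization of fluorescence time courses, two-anchor
    percent-of-stress normalization, Dunnett many-to-one hit calling with a
    fast multivariate-t quadrature, selectivity classification of hits, and
    Spearman correlation across endpoints, together with a fully synthetic
    extract-library generator for end-to-end testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    optparse
Config/testthat/edition: 3
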