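Package: rootTDA
Title: Topological Analysis of Plant Root System Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the topological analysis of plant root system
    architectures. Reads and writes Root System Markup Language (RSML)
    files, flattens root systems into per-segment tables with geodesic
    distances, computes zero-order persistent homology barcodes of the
    geodesic distance function by the elder rule, compares barcodes with
    an exact bottleneck distance, derives Fitter's topological indices
    (magnitude, altitude, external path length) and a panel of aggregated
    architectural traits, and embeds pairwise barcode dissimilarities by
    non-metric multidimensional scaling. A seeded generator of
    ArchiSimple-style synthetic root systems (fibrous and tap-rooted
    habits, seven single-parameter genotype presets) provides reproducible
    test libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    xml2,
    vegan,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
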