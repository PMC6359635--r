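Package: goldmap
Title: Quantification of Immunogold Labelling in Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying subcellular immunogold labelling in
    annotated electron-microscopy scenes: arc-length parameterisation of
    membrane contours, projection of gold particles onto the plasma
    membrane, classification into membrane-associated versus intracellular
    pools and pre- versus postsynaptic compartments, binning of arc
    distances from the edge of the postsynaptic density, somato-dendritic
    density gradients, nonparametric group comparisons (two-sample
    Kolmogorov-Smirnov with a block-pooling rule, Kruskal-Wallis with
    Dunn's post hoc test), and circular-cursor histoblot densitometry with
    eight-point background correction. A synthetic ultrastructure-scene
    generator with frozen reference presets makes every pipeline stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    pracma,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
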