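Package: neuritescreen
Title: Image-Based Screening of Neurite Alignment and Differentiation on
    Nanogrooved Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-content screening of neuronal cultures grown on nanogrooved
    substrates from multi-channel fluorescence micrographs. Detects somata and
    neurites, traces and links neurites to cells, and measures per-image
    morphometric variables (cell counts, differentiated fraction, neurite
    length, polarity, branching). Quantifies neurite alignment to the groove
    direction with a multiscale Frangi vesselness orientation field on
    neurite-only images, cross-checked by Fourier-spectrum directionality and
    a per-neurite chord measurement. Includes a seeded synthetic-image
    generator with complete ground truth and a nonparametric statistics layer
    (Lilliefors, Kruskal-Wallis with Dunn's post hoc, Spearman, median/IQR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
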