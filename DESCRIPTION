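Package: comboloc
Type: Package
Title: Localization Microscopy Analysis of COMBO-FISH Labelled Repeat Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-molecule localization microscopy (SMLM/SPDM) of
    COMBO-FISH labelled ALU repeats combined with heterochromatin
    immunostaining: spot detection and moment-based sub-pixel localization
    from raw image stacks, super-resolution rendering (pointillist, density
    and localization images), DBSCAN cluster detection with shoelace-formula
    cluster centers, concentric-shell density profiling of the chromatin
    environment, oligonucleotide probe design by exact k-mer genome scanning,
    quadratic dose-response fitting for biological dosimetry, and seeded
    synthetic-data generators for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    jsonlite,
    yaml,
    tiff,
    igraph,
    mgcv,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
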