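Package: specklemix
Title: Non-Invasive Transmission-Matrix Recovery from Fluorescence Speckle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and reconstruction toolkit for non-invasive
    wavefront shaping with linear fluorescence feedback. Simulates
    epi-detected fluorescence speckle stacks produced by random phase
    patterns sent through a scattering medium onto a multi-emitter
    fluorescent object, then recovers the outgoing intensity transmission
    matrix by non-negative matrix factorization, the ingoing field
    transmission matrix by intensity-only phase retrieval with spectral
    initialization, focuses by phase conjugation with a non-invasive
    variance-based validation, and images extended objects beyond the
    memory-effect range by cross-correlation stitching of fluorescent
    eigen-patterns or multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
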