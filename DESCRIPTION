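Package: assemblymotifs
Title: Cross-Regional Cell Assembly Detection and Loop-Like Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects lagged pair and triplet cell assemblies in parallel
    spike trains recorded across brain areas, classifies them into
    directional and loop-like motifs relative to a focal area (by default
    the zona incerta), and quantifies cross-regional coordination with
    combinatorially normalized assembly probabilities, an internal-versus-
    external coupling index, exact binomial asymmetry tests with
    combinatorial nulls, and circular-shift surrogate controls. Includes a
    seeded synthetic spike-train generator with planted assemblies so that
    detection, classification and statistics can be validated against
    ground truth, plus graph exports of the inferred functional networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
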