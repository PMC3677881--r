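Package: hubtopo
Title: Topographic Hub Mapping of Structural Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Template-free hub mapping for structural brain networks. Builds
    streamline-count connectomes over ensembles of random k-means parcellations,
    computes node degree and betweenness centrality, projects them into voxelwise
    topographic hub maps, extracts peak-separated hub regions with per-subject hub
    scores, and tests hemispheric asymmetry, sex differences and small-world
    topology (degree-preserving null models). Ships a synthetic cohort generator
    with planted connector and provincial hub zones so the whole pipeline can be
    validated end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
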