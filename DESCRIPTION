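Package: semfluency
Title: Semantic Network Analysis of Verbal Fluency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates group-level semantic networks from verbal (semantic)
    fluency transcripts and compares them between participant groups.
    Provides cleaning of raw fluency lists against a category lexicon,
    binary response matrices, cosine-similarity edge estimation with
    triangulated maximally filtered graph (TMFG) sparsification, global
    and local graph metrics with Erdos-Renyi and node-wise bootstrap
    inference, spreading-activation simulation, weighted k-clique
    percolation with a resilience integral, and a synthetic cohort
    generator with known ground truth so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
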