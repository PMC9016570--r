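Package: disco
Title: Decomposition of Multicopy Gene Family Trees into Single-Copy Trees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes multicopy (MUL) gene family trees into leaf-disjoint
    single-copy trees. Each input tree is rooted on the edge minimizing a
    duplication-plus-loss parsimony score, internal vertices are tagged as
    speciation or duplication by species-set overlap, and duplication
    vertices are resolved bottom-up by splitting off the child clade with
    fewer species (DISCO). Also provides the maximum-inclusive-subtree (MI)
    baseline decomposition, construction of partitioned concatenation
    supermatrices from per-family alignments (CA-DISCO), orthology
    precision/recall and normalized Robinson-Foulds evaluation utilities,
    and a birth-death gene duplication/loss simulator for generating
    species trees, event-labeled gene family trees, and clade-based
    missing-data scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
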