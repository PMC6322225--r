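Package: pxpn
Title: Pathway Crosstalk Perturbation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pathway crosstalk perturbation networks (PXPNs): graphs
    whose nodes are gene-expression-perturbed pathways and whose edges are
    perturbed crosstalk regions (the gene-set intersections of pathway
    pairs). Provides GMT and GML input/output, a pluggable two-sample
    gene-set enrichment with Benjamini-Hochberg control, topological
    summaries (density, specific density, clustering, path lengths,
    components, Infomap communities and their quotient graph), two null
    models (a Jaccard-weighted edge-rewiring ensemble with Z-tests and a
    gene-label-shuffling ensemble with trivial-structure classification),
    and a synthetic-data generator with planted pathway and crosstalk
    perturbations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
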