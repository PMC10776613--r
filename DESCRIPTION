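Package: wormid
Title: Automated Cell-Identity Annotation and Single-Cell Reporter
    Profiling for C. elegans L1 Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates the 558 cells of newly hatched C. elegans L1
    larvae in 3D nuclear-centroid point clouds. Builds statistical
    position templates (digital worms) from annotated training animals,
    registers new animals by PCA pre-alignment, deterministic-annealing
    robust point matching and sliding-window piecewise-affine remapping,
    assigns identities by maximum-score bipartite matching under an
    anisotropic Gaussian position model, and reports per-cell and
    per-worm annotation confidence with threshold-based error flagging.
    Also quantifies nuclear reporter fluorescence into per-cell
    expression levels, aggregates transcription-factor profiles, and
    provides profile analytics: bootstrap-supported hierarchical
    clustering, parsimony subtyping on the dendrogram, Jensen-Shannon
    divergences, and detectors for region-specific, gradient,
    lineage-related and left-right asymmetric expression patterns.
    Ground-truthed synthetic worms and expression stacks make the whole
    pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
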