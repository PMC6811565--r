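Package: coexpharm
Title: Consensus Co-Expression Modules and Network-Proximity Drug
    Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds consensus weighted gene co-expression networks across
    several tissue expression datasets, detects modules that are preserved
    in every tissue (signed adjacency, topological overlap, minimum
    consensus, hybrid tree cut), quantifies module stability under sample
    perturbation, summarises modules by eigengenes and groups them into
    meta-modules, scores disease association through gene significance and
    intramodular connectivity, and extracts a disease gene signature that
    is screened against a protein-protein interactome: drugs are ranked by
    closest-distance network proximity of their targets to the signature,
    with degree-preserving randomisation providing z-scores, and Fisher
    exact tests validating the ranked lists. A synthetic-data generator
    with known ground truth (planted co-expression modules, trait-shifted
    latent factors, scale-free interactome with a planted disease
    neighbourhood, proximal and distal drug target sets) supports recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
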