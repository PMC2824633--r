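Package: perturbnet
Title: Differential Functional Annotation of Gene-Knockdown Expression
    Profiles via Enrichment and Protein-Interaction Network Nulls
Version: 0.1.0
Authors@R: person("perturbnet", "maintainers", email = "maintainers@perturbnet.org",
    role = c("aut", "cre"))
Description: A tested pipeline for assigning differential functions to
    gene-knockdown conditions from expression ratio tables: fold-change
    deregulated-gene calling with probe-to-gene collapsing, category
    over-representation with one-sided Fisher's exact tests and a
    randomization false-discovery rate, fixed-collection pathway testing
    with Bonferroni correction, depth-1-plus expansion of target sets
    through a protein-protein interaction graph, and an empirical
    random-network null for network-level pathway enrichment.  Includes
    comparative-CT (delta-delta-CT) qPCR quantification with multi-reference
    geometric-mean normalization, and a synthetic-data module that generates
    expression tables, interactomes, annotation catalogs and qPCR plates
    with known planted structure.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
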