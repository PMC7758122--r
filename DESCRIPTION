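Package: netpharm
Title: Network Pharmacology Inference for Compound-Target-Pathway Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology analysis of multi-component
    preparations: thermodynamic conversion between inhibition constants and
    docking binding free energies, threshold filtering of docking tables,
    integration of database- and docking-evidenced compound-target
    interactions, construction of compound-target (CTN), target-pathway (TPN)
    and compound-target-pathway (CTPN) networks, from-scratch degree,
    betweenness (Brandes) and closeness centrality, centrality-based screening
    of key targets and important pathways, a seeded tripartite synthetic-data
    generator, and a one-call pipeline with a machine-readable report.
    Ships transcriptions of the ingredient and docking tables of the Reduning
    Injection (RDNI) study as packaged fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
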