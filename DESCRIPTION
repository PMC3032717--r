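Package: immunet
Title: Agent-Based Immune Response Simulation and Dynamic Contact-Network Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-compartment lattice agent-based model of the innate and
    adaptive immune response to a viral infection of a generic tissue.  Nine
    agent types (parenchymal tissue cells, portals, dendritic cells,
    macrophages, natural killer cells, granulocytes, T cells, B cells and
    cytotoxic T lymphocytes) follow finite-state-automaton rules on square
    lattices representing organ tissue, secondary lymphoid tissue and blood,
    with diffusing cytokine, chemokine, virus and antibody signal fields,
    chemotaxis, and portal-mediated migration between compartments.  Every
    "meaningful" agent-agent contact (one that changes an agent's state or an
    internal variable) is recorded in per-agent ledgers and checkpointed to
    CSV, turning each run into a dynamic contact network.  The package
    provides run/batch/sweep orchestration with win/loss outcome
    classification, engagement time courses, links-per-node distributions with
    log-log power-law (scale-free) checks via Spearman correlation and linear
    regression, hub identification, Mann-Whitney U comparisons with Bonferroni
    correction, and calibration of simulation ticks to physical time from
    immune-response hallmark timings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    data.table,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
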