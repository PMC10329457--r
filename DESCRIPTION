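Package: syncomr
Title: Deconstruction of Synthetic Bacterial Communities and Their Effects on Root Growth
Version: 0.1.0
Authors@R:
    person("SynCom", "Tools", email = "syncomr@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for stepwise deconstruction of plant-associated
    synthetic bacterial communities (SynComs). Detects modules of co-occurring
    strains from relative-abundance profiles (correlation dissimilarity and
    Ward clustering, with hypergeometric family enrichment), discovers
    clade-specific genomic hotspots from orthogroup presence/absence and gene
    coordinates, classifies root-growth-inhibition (RGI) phenotypes and tests
    reversion by candidate suppressor strains, runs a gene-set resampling test
    for marker-gene expression shifts, and applies prevalence rules for
    widespread and core taxa in amplicon surveys. Ships simulators for every
    input with recorded ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
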