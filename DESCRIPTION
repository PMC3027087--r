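Package: crvnet
Title: Differential Protein Association Networks for Network-Based Biomarkers
Version: 0.1.0
Authors@R:
    person("crvnet", "developers", email = "crvnet@example.org",
           role = c("aut", "cre"))
Description: Infers phenotype-specific protein association networks by
    integrating expression profiles with protein-protein interaction data,
    scores each protein's disease relevance from the difference between the
    two networks (carcinogenesis relevance value, CRV) with an empirical
    permutation null, and classifies new samples by their mapping error
    against the two networks. Includes a model-consistent synthetic-data
    generator, a stage-based pipeline runner with a command-line interface,
    and readers for tab-delimited expression matrices, BioGRID TAB2, HPRD
    and generic edge-list interaction files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
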