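Package: ctuscope
Title: Candidate Taxonomic Unit Circumscription for Uncultured Marine Microbes
Version: 0.1.0
Authors@R: person("ctuscope", "developers", role = c("aut", "cre"),
    email = "ctuscope@example.org")
Description: Delineates candidate taxonomic units (CTUs) for uncultured marine
    water-column microbes from SSU rRNA data. Mines marine environmental
    sequences from SILVA-style records using keyword rules and quality filters,
    clusters sequences with hierarchical furthest-neighbor (complete-linkage)
    clustering at rank-specific identity thresholds (phylum to genus),
    reconciles the resulting nested OTU partitions with a phylogenetic tree
    into monophyletic, standardly named candidate taxa, masks clades already
    known from the literature, and screens clade-by-sample abundance tables
    for site associations (one-sided permutation tests) and Spearman
    correlations with environmental gradients. Ships a seed-deterministic
    synthetic-data generator with planted rank structure and planted
    ecological effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
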